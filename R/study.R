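#' Simulate a complete rearrangement study
#'
#' Generates a toy genome, plants canonical V(D)J events (coding + signal
#' joints), RSS-bearing and RSS-free ectopic SVs, germline SVs shared with
#' the matched control, an optional BFB amplicon, windowed tumor/control
#' read depth, and noisy multi-caller call sets -- all with machine-readable
#' ground truth.  Everything is a pure function of the configuration seed.
#'
#' @param config A [sim_config()].
#' @param n_callers,sensitivity,jitter_sd,fp_per_caller Caller-noise model
#'   passed to [simulate_caller_outputs()].
#' @return List with `genome`, `truths` (somatic, junction-bearing),
#'   `germline_truths`, `caller_output`, `cn_profile`, `depth`, `bfb`
#'   (NULL or the [simulate_bfb()] result), and `config`.
#' @export
simulate_rearrangement_study <- function(config, n_callers = 3L,
                                         sensitivity = 0.95,
                                         jitter_sd = 50,
                                         fp_per_caller = 5L) {
  genome <- generate_genome(config)   # seeds the RNG from config$seed
  truths <- list()

  # canonical V(D)J events from convergent canonical planting pairs
  pairs <- pair_canonical_sites(genome, config$n_vdj_events)
  for (p in pairs) {
    res <- simulate_vdj_event(genome, genome$planted_rss[p, ], config)
    genome <- res$genome
    genome$planted_rss$used[p] <- TRUE
    genome <- mark_used(genome, genome$planted_rss$chrom[p[1]],
                        genome$planted_rss$offset[p[1]])
    genome <- mark_used(genome, genome$planted_rss$chrom[p[2]],
                        genome$planted_rss$offset[p[2]])
    truths <- c(truths, res$truths)
  }

  add_ectopic <- function(n, rss_mode, germline) {
    classes <- draw_sv_classes(n, config)
    for (cl in classes) {
      res <- simulate_ectopic_sv(genome, cl, rss_mode, config,
                                 germline = germline)
      genome <<- res$genome
      if (germline) germline_truths <<- c(germline_truths, list(res$truth))
      else truths <<- c(truths, list(res$truth))
    }
  }
  germline_truths <- list()
  add_ectopic(config$n_ectopic_rss, "both", FALSE)
  add_ectopic(config$n_ectopic_plain, "none", FALSE)
  add_ectopic(config$n_germline, "none", TRUE)

  bfb_res <- NULL
  if (!is.null(config$bfb)) {
    bfb_res <- simulate_bfb(genome, config$bfb, config)
    genome <- bfb_res$genome
    truths <- c(truths, bfb_res$truths)
  }

  cn <- flat_cn_profile(genome, config$window_size)
  if (!is.null(bfb_res)) {
    bchrom <- config$bfb$chromosome
    cn <- cn[cn$chrom != bchrom, , drop = FALSE]
    cn <- rbind(cn, bfb_res$cn_profile[, c("chrom", "window_start",
                                           "copy_number")])
    cn <- cn[order(cn$chrom, cn$window_start), , drop = FALSE]
    rownames(cn) <- NULL
  }
  depth <- simulate_read_depth(cn, config$coverage_mean)

  caller_output <- simulate_caller_outputs(
    truths, genome, n_callers = n_callers, sensitivity = sensitivity,
    jitter_sd = jitter_sd, fp_per_caller = fp_per_caller,
    germline_truths = germline_truths)

  list(genome = genome, truths = truths,
       germline_truths = germline_truths,
       caller_output = caller_output,
       cn_profile = cn, depth = depth, bfb = bfb_res, config = config)
}

flat_cn_profile <- function(genome, window_size) {
  out <- lapply(names(genome$chromosomes), function(chrom) {
    starts <- seq(0, nchar(genome$chromosomes[[chrom]]) - 1,
                  by = window_size)
    data.frame(chrom = chrom, window_start = as.integer(starts),
               copy_number = 2L, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Greedily pair unused canonical '+' plantings with the nearest downstream
# unused canonical '-' planting (>= 2 kb away, same chromosome).
pair_canonical_sites <- function(genome, n_pairs, min_gap = 2000L) {
  df <- genome$planted_rss
  pairs <- list()
  used <- df$used
  for (chrom in unique(df$chrom)) {
    fw <- which(df$chrom == chrom & df$orientation == "+" &
                df$is_canonical & !used)
    rv <- which(df$chrom == chrom & df$orientation == "-" &
                df$is_canonical & !used)
    for (i in fw) {
      if (length(pairs) >= n_pairs) break
      cand <- rv[df$offset[rv] >= df$offset[i] + min_gap & !used[rv]]
      if (!length(cand)) next
      j <- cand[which.min(df$offset[cand])]
      used[c(i, j)] <- TRUE
      pairs <- c(pairs, list(c(i, j)))
    }
    if (length(pairs) >= n_pairs) break
  }
  if (length(pairs) < n_pairs) {
    stop("only ", length(pairs), " convergent canonical RSS pairs available; ",
         "increase n_canonical_rss or chromosome lengths")
  }
  pairs
}

#' Truth records as a flat table
#'
#' @param truths List of `sv_truth` records.
#' @return data.frame with the SV coordinates, class, chemistry and joint
#'   annotation of every truth.
#' @export
truth_table <- function(truths) {
  rows <- lapply(seq_along(truths), function(i) {
    t <- truths[[i]]
    cbind(sv_id = sprintf("sv%04d", i), t$sv[, c("chrom1", "pos1", "chrom2",
                                                 "pos2", "sv_class")],
          data.frame(chemistry = t$chemistry,
                     microhomology_len = t$microhomology_len,
                     inserted_bases = t$inserted_bases,
                     vdj_joint_type = t$vdj_joint_type %||% NA_character_,
                     germline = isTRUE(t$germline),
                     junction_sequence = t$junction_sequence,
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
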