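# Breakage-fusion-bridge simulation.  The rearranged chromatid is tracked
# as an ordered list of signed reference segments (0-based half-open).  Each
# cycle: the broken end fuses with its sister chromatid (broken a small
# offset d earlier; the fusion is a fold-back inversion with breakpoint
# distance d), the resulting dicentric bridge ruptures at a position drawn
# below the fusion point, and the daughter retaining both copies of the
# fusion-proximal region is followed (the amplified clone is the one that is
# sequenced).  Copy number therefore doubles over the interval between
# successive breaks, building the characteristic staircase.

seg_df <- function(start, end, sign) {
  data.frame(start = as.numeric(start), end = as.numeric(end),
             sign = as.integer(sign))
}

seg_len <- function(segs) sum(segs$end - segs$start)

seg_reverse_flip <- function(segs) {
  out <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  out$sign <- -out$sign
  rownames(out) <- NULL
  out
}

# Keep the first `keep` bp of the structure.
seg_truncate_right <- function(segs, keep) {
  lens <- segs$end - segs$start
  cum <- cumsum(lens)
  i <- which(cum >= keep)[1]
  out <- segs[seq_len(i), , drop = FALSE]
  excess <- cum[i] - keep
  if (excess > 0) {
    if (out$sign[i] > 0) out$end[i] <- out$end[i] - excess
    else out$start[i] <- out$start[i] + excess
  }
  rownames(out) <- NULL
  out
}

seg_string <- function(segs, chrom) {
  paste(sprintf("%s:%d-%d:%s", chrom, as.integer(segs$start),
                as.integer(segs$end), ifelse(segs$sign > 0, "+", "-")),
        collapse = " ")
}

#' Multiplicity of reference windows under a signed segment structure
#'
#' Independent of the simulator bookkeeping: walks the segment list and
#' accumulates base-pair coverage per fixed-size window.
#'
#' @param segs data.frame(start, end, sign) or a segment string as produced
#'   by [simulate_bfb()].
#' @param chrom_length Chromosome length in bp.
#' @param window_size Window size in bp.
#' @return data.frame(window_start, bp, multiplicity) where multiplicity is
#'   bp coverage / window size rounded to the nearest integer.
#' @export
segment_multiplicity <- function(segs, chrom_length, window_size = 50000L) {
  if (is.character(segs)) {
    parts <- strsplit(strsplit(segs, " ", fixed = TRUE)[[1]], ":",
                      fixed = TRUE)
    rng <- t(vapply(parts, function(p) {
      se <- as.numeric(strsplit(p[2], "-", fixed = TRUE)[[1]])
      c(se[1], se[2], if (p[3] == "+") 1 else -1)
    }, numeric(3)))
    segs <- seg_df(rng[, 1], rng[, 2], rng[, 3])
  }
  starts <- seq(0, chrom_length - 1, by = window_size)
  bp <- numeric(length(starts))
  for (i in seq_len(nrow(segs))) {
    s <- segs$start[i]; e <- segs$end[i]
    lo <- pmax(starts, s)
    hi <- pmin(starts + window_size, e)
    bp <- bp + pmax(hi - lo, 0)
  }
  data.frame(window_start = as.integer(starts), bp = bp,
             multiplicity = as.integer(round(bp / window_size)))
}

#' Simulate breakage-fusion-bridge cycles
#'
#' Iterates `n_cycles` of break -> sister-chromatid fusion (emitting one
#' fold-back inversion truth per fusion) -> jittered bridge rupture, then
#' reports the per-window copy-number profile, the fold-back (and terminal
#' loss) truth records, and the final chromatid as a signed segment string.
#'
#' The returned `cn_profile` gives total tumor copy number per window
#' assuming one intact homolog (rearranged-chromatid multiplicity + 1);
#' the raw multiplicity is also included.
#'
#' @param genome A `toy_genome`.
#' @param bfb A [bfb_config()].
#' @param config A [sim_config()].
#' @return List: `cn_profile` (chrom, window_start, multiplicity,
#'   copy_number), `truths` (fold-back inversions plus the terminal-loss
#'   deletion), `segments` (data.frame), `segment_string`, and the updated
#'   `genome`.
#' @export
simulate_bfb <- function(genome, bfb, config) {
  stopifnot(inherits(bfb, "bfb_config"))
  chrom <- bfb$chromosome
  L <- nchar(genome$chromosomes[[chrom]])
  ws <- config$window_size
  b0 <- bfb$initial_break %||% round(0.75 * L)
  if (b0 <= 0 || b0 >= L) stop("initial_break outside the chromosome")

  segs <- seg_df(0, b0, 1L)
  e <- b0                      # reference coordinate of the broken end
  truths <- list()

  for (cycle in seq_len(bfb$n_cycles)) {
    d <- round(min(max(40, abs(stats::rnorm(1, 0, bfb$break_position_jitter))),
                   2 * bfb$break_position_jitter))
    last_sign <- segs$sign[nrow(segs)]
    if (last_sign > 0) {
      sv <- new_sv_call(chrom, e - d, chrom, e, "INV",
                        orient1 = "+", orient2 = "-")
    } else {
      sv <- new_sv_call(chrom, e, chrom, e + d, "INV",
                        orient1 = "-", orient2 = "+")
    }
    # fold-back chemistry
    u <- stats::runif(1)
    chem <- if (u < bfb$foldback_mh_prob) {
      list(type = "microhomology",
           m = sample.int(config$microhomology_max, 1L), ins_len = 0L)
    } else if (u < bfb$foldback_mh_prob + bfb$foldback_ins_prob) {
      list(type = "insertion", m = 0L, ins_len = sample.int(10L, 1L))
    } else {
      list(type = "blunt", m = 0L, ins_len = 0L)
    }
    pc <- plant_chemistry(genome, sv, chem)
    genome <- pc$genome
    truths <- c(truths, list(new_sv_truth(genome, sv, pc$ins)))

    # fuse with the sister broken d bp earlier, then rupture the bridge
    sister <- seg_truncate_right(segs, seg_len(segs) - d)
    appended <- seg_reverse_flip(sister)
    sister_end <- if (last_sign > 0) e - d else e + d
    g <- NA
    for (attempt in 1:100) {
      cand <- round(sister_end - 50 - abs(stats::rnorm(1, 0, bfb$bridge_break_sd)))
      if (cand >= ws && cand <= sister_end - 50) { g <- cand; break }
    }
    if (is.na(g)) stop("bridge break position outside chromosome after 100 attempts")
    # the final appended segment is the reversed copy of the initial
    # [0, b0) segment; rupture it at reference coordinate g
    n <- nrow(appended)
    stopifnot(appended$sign[n] < 0, appended$start[n] < g)
    appended$start[n] <- g
    segs <- rbind(segs, appended)
    rownames(segs) <- NULL
    e <- g
  }

  # terminal loss distal to the initial break (no junction exists)
  term <- structure(list(
    sv = new_sv_call(chrom, b0, chrom, L - 1L, "DEL"),
    junction_sequence = NA_character_, join = NA_integer_,
    chemistry = "blunt", microhomology_len = 0L, inserted_bases = "",
    context = NULL, rss_left = NA_integer_, rss_right = NA_integer_,
    vdj_joint_type = NA_character_, germline = FALSE, terminal = TRUE),
    class = "sv_truth")
  truths <- c(truths, list(term))

  mult <- segment_multiplicity(segs, L, ws)
  cn <- data.frame(chrom = chrom, window_start = mult$window_start,
                   multiplicity = mult$multiplicity,
                   copy_number = mult$multiplicity + 1L,
                   stringsAsFactors = FALSE)
  list(cn_profile = cn, truths = truths, segments = segs,
       segment_string = seg_string(segs, chrom), genome = genome)
}

#' Simulate a tandem-duplication-driven amplicon (BFB-negative control)
#'
#' Stacks `n_copies` extra tandem copies of a region, emitting one DUP
#' junction truth per copy and the corresponding copy-number profile, with
#' no fold-back inversions.
#'
#' @param genome A `toy_genome`.
#' @param chrom Chromosome name.
#' @param region c(start, end) of the duplicated unit.
#' @param n_copies Number of extra copies (region copy number = 2 + n).
#' @param config A [sim_config()].
#' @return List with `cn_profile`, `truths`, and the updated `genome`.
#' @export
simulate_dup_amplicon <- function(genome, chrom, region, n_copies = 3L,
                                  config) {
  L <- nchar(genome$chromosomes[[chrom]])
  ws <- config$window_size
  truths <- list()
  for (i in seq_len(n_copies)) {
    # each copy joins region end back to a jittered region start
    p1 <- round(region[1] + abs(stats::rnorm(1, 0, 2 * ws)))
    p2 <- round(region[2] - abs(stats::rnorm(1, 0, 2 * ws)))
    sv <- new_sv_call(chrom, p1, chrom, p2, "DUP", orient1 = "-",
                      orient2 = "-")
    chem <- draw_chemistry(config, config$insertion_fraction_plain)
    pc <- plant_chemistry(genome, sv, chem)
    genome <- pc$genome
    truths <- c(truths, list(new_sv_truth(genome, sv, pc$ins)))
  }
  starts <- seq(0, L - 1, by = ws)
  mult <- rep(1L, length(starts))
  for (t in truths) {
    lo <- t$sv$pos1; hi <- t$sv$pos2
    ov <- pmax(pmin(starts + ws, hi) - pmax(starts, lo), 0)
    mult <- mult + as.integer(round(ov / ws))
  }
  cn <- data.frame(chrom = chrom, window_start = as.integer(starts),
                   multiplicity = mult, copy_number = mult + 1L,
                   stringsAsFactors = FALSE)
  list(cn_profile = cn, truths = truths, genome = genome)
}

#' Simulate windowed read depth for tumor and matched diploid control
#'
#' Tumor window counts are Poisson(coverage_mean * CN / 2); control counts
#' are Poisson(coverage_mean).
#'
#' @param cn_profile data.frame with columns chrom, window_start,
#'   copy_number.
#' @param coverage_mean Expected count per window at copy number 2.
#' @param seed Optional integer seed for reproducible tables.
#' @return data.frame(chrom, window_start, tumor_count, control_count).
#' @export
simulate_read_depth <- function(cn_profile, coverage_mean, seed = NULL) {
  if (coverage_mean <= 0) stop("coverage_mean must be > 0")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cn_profile)
  data.frame(chrom = cn_profile$chrom,
             window_start = cn_profile$window_start,
             tumor_count = stats::rpois(n, coverage_mean *
                                          cn_profile$copy_number / 2),
             control_count = stats::rpois(n, coverage_mean),
             stringsAsFactors = FALSE)
}
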