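# Emulated output of multiple SV callers run on a simulated tumor/control
# pair: per-caller sensitivity, Gaussian breakpoint jitter, Poisson-ish
# read-pair support, uniform false positives, and germline calls shared
# with the matched control.  One caller per run is designated "precise" and
# reports exact breakpoints (mirroring split-read callers).

truths_to_calls <- function(truths, caller = "truth") {
  svs <- lapply(truths, function(t) t$sv)
  if (!length(svs)) {
    return(new_sv_call("chr0", 0, "chr0", 1, "DEL")[0, ])
  }
  df <- do.call(rbind, svs)
  df$caller <- caller
  rownames(df) <- NULL
  df
}

#' Simulate per-caller tumor call sets and a matched control call set
#'
#' Each caller detects each somatic and germline truth independently with
#' probability `sensitivity`, reports breakpoints with Gaussian jitter
#' (sd = `jitter_sd`, truncated inside the chromosome), read-pair support
#' 3 + Poisson(5), and adds `fp_per_caller` uniformly placed false
#' positives.  Caller `precise_caller` reports zero jitter and flags its
#' calls precise.  Germline truths also appear, jitter-free with support
#' >= 1, in the control call set.  Terminal-loss truths (no junction, no
#' discordant pairs) are not visible to read-pair callers and are skipped.
#'
#' @param truths List of somatic `sv_truth` records.
#' @param genome A `toy_genome` (for chromosome bounds and FP placement).
#' @param n_callers Number of callers (>= 1).
#' @param sensitivity Per-caller detection probability (scalar or one per
#'   caller).
#' @param jitter_sd Breakpoint jitter sd in bp for imprecise callers.
#' @param fp_per_caller False positives added per caller.
#' @param germline_truths List of germline `sv_truth` records.
#' @param precise_caller Index of the zero-jitter caller.
#' @param seed Optional seed.
#' @return List: `tumor` (named list of per-caller SV data.frames) and
#'   `control` (SV data.frame).
#' @export
simulate_caller_outputs <- function(truths, genome, n_callers = 3L,
                                    sensitivity = 0.95, jitter_sd = 50,
                                    fp_per_caller = 5L,
                                    germline_truths = list(),
                                    precise_caller = n_callers,
                                    seed = NULL) {
  if (n_callers < 1) stop("n_callers must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sensitivity <- rep_len(sensitivity, n_callers)
  callers <- sprintf("caller%02d", seq_len(n_callers))
  keep <- vapply(truths, function(t) !isTRUE(t$terminal), logical(1))
  truths <- truths[keep]
  all_truths <- c(truths, germline_truths)
  base_calls <- truths_to_calls(all_truths)
  lens <- nchar(genome$chromosomes)

  jitter_pos <- function(pos, chrom, sd) {
    if (sd <= 0) return(pos)
    p <- pos + round(stats::rnorm(length(pos), 0, sd))
    pmin(pmax(p, 30L), lens[chrom] - 30L)
  }

  tumor <- stats::setNames(vector("list", n_callers), callers)
  for (i in seq_len(n_callers)) {
    precise <- i == precise_caller
    sd <- if (precise) 0 else jitter_sd
    det <- stats::runif(nrow(base_calls)) < sensitivity[i]
    calls <- base_calls[det, , drop = FALSE]
    if (nrow(calls)) {
      calls$pos1 <- as.integer(jitter_pos(calls$pos1, calls$chrom1, sd))
      calls$pos2 <- as.integer(jitter_pos(calls$pos2, calls$chrom2, sd))
      swap <- calls$chrom1 == calls$chrom2 & calls$pos1 > calls$pos2
      if (any(swap)) {
        tmp <- calls$pos1[swap]
        calls$pos1[swap] <- calls$pos2[swap]
        calls$pos2[swap] <- tmp
      }
      calls$support <- 3L + stats::rpois(nrow(calls), 5)
      calls$caller <- callers[i]
      calls$precise <- precise
    }
    if (fp_per_caller > 0) {
      fp <- lapply(seq_len(fp_per_caller), function(k) {
        chrom <- sample(names(lens), 1, prob = lens)
        span <- sample(5000:100000, 1)
        p1 <- sample.int(max(lens[[chrom]] - span - 2000L, 1L), 1) + 1000L
        new_sv_call(chrom, p1, chrom, p1 + span,
                    sample(c("DEL", "DUP", "INV"), 1),
                    support = 3L + stats::rpois(1, 5),
                    caller = callers[i], precise = precise)
      })
      calls <- rbind(calls, do.call(rbind, fp))
    }
    rownames(calls) <- NULL
    tumor[[i]] <- calls
  }

  control <- truths_to_calls(germline_truths, caller = "control")
  if (nrow(control)) {
    control$support <- 1L + stats::rpois(nrow(control), 4)
    control$precise <- FALSE
  }
  list(tumor = tumor, control = control)
}
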