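# Cross-caller SV integration: matching, single-linkage consensus,
# germline subtraction against a matched control, and support filtering.
# Retention rule: intra-chromosomal variants predicted by at least two
# callers, inter-chromosomal variants by at least three.

# Canonical breakpoint order: intra pos1 <= pos2; inter (chrom1, pos1) <=
# (chrom2, pos2) lexicographically, so translocation chromosome pairs
# compare unordered.
canonicalize_calls <- function(calls) {
  if (!nrow(calls)) return(calls)
  swap <- (calls$chrom1 == calls$chrom2 & calls$pos1 > calls$pos2) |
          (calls$chrom1 > calls$chrom2)
  if (any(swap)) {
    tmp_c <- calls$chrom1[swap]; tmp_p <- calls$pos1[swap]
    tmp_o <- calls$orient1[swap]
    calls$chrom1[swap] <- calls$chrom2[swap]
    calls$pos1[swap] <- calls$pos2[swap]
    calls$orient1[swap] <- calls$orient2[swap]
    calls$chrom2[swap] <- tmp_c
    calls$pos2[swap] <- tmp_p
    calls$orient2[swap] <- tmp_o
  }
  calls
}

effective_window <- function(precise, window) {
  ifelse(precise, pmin(window, 10), window)
}

#' Do two SV calls match?
#'
#' True iff the chromosome pairs are equal (unordered for translocations),
#' both breakpoints lie within the matching window, and the SV classes
#' agree when both calls are intra-chromosomal (class comparison is waived
#' for germline subtraction, where caller conventions differ).  A call
#' flagged precise has an effective window of min(window, 10); two calls
#' are compared at the larger of their effective windows, so a precise call
#' can sit anywhere inside an imprecise call's uncertainty.
#'
#' @param a,b One-row SV data.frames.
#' @param window Matching window in bp (>= 0).
#' @param require_class Compare sv_class for intra-chromosomal pairs.
#' @return Logical.
#' @export
match_calls <- function(a, b, window = 150, require_class = TRUE) {
  stopifnot(window >= 0)
  a <- canonicalize_calls(a)
  b <- canonicalize_calls(b)
  if (a$chrom1 != b$chrom1 || a$chrom2 != b$chrom2) return(FALSE)
  intra_a <- a$chrom1 == a$chrom2
  intra_b <- b$chrom1 == b$chrom2
  if (require_class && intra_a && intra_b && a$sv_class != b$sv_class) {
    return(FALSE)
  }
  w <- max(effective_window(isTRUE(a$precise), window),
           effective_window(isTRUE(b$precise), window))
  abs(a$pos1 - b$pos1) <= w && abs(a$pos2 - b$pos2) <= w
}

# Vectorized matching of one call against a table of calls (all already
# canonicalized).
match_many <- function(call, calls, window, require_class = TRUE) {
  ok <- calls$chrom1 == call$chrom1 & calls$chrom2 == call$chrom2
  if (require_class && call$chrom1 == call$chrom2) {
    intra <- calls$chrom1 == calls$chrom2
    ok <- ok & (!intra | calls$sv_class == call$sv_class)
  }
  w <- pmax(effective_window(isTRUE(call$precise), window),
            effective_window(calls$precise, window))
  ok & abs(calls$pos1 - call$pos1) <= w & abs(calls$pos2 - call$pos2) <= w
}

#' Cross-caller consensus of SV calls
#'
#' Single-linkage clusters of matching calls across callers.  A cluster is
#' retained iff it is intra-chromosomal and supported by at least
#' `min_callers_intra` distinct callers, or inter-chromosomal and supported
#' by at least `min_callers_inter`.  The representative coordinates are the
#' (lexicographically first) precise member's if any caller resolved the
#' cluster precisely, else the support-weighted median per breakpoint.
#'
#' @param calls_by_caller Named list of SV data.frames, one per caller.
#' @param window Matching window in bp.
#' @param min_callers_intra,min_callers_inter Retention thresholds.
#' @return Consensus SV data.frame, sorted by (chrom1, pos1), with columns
#'   of the representative call plus `n_callers`, `supporting_callers` and
#'   `best_support`.
#' @export
consensus <- function(calls_by_caller, window = 150,
                      min_callers_intra = 2L, min_callers_inter = 3L) {
  stopifnot(length(calls_by_caller) >= 1)
  # deterministic regardless of input order
  calls_by_caller <- calls_by_caller[order(names(calls_by_caller))]
  all_calls <- do.call(rbind, unname(calls_by_caller))
  empty <- cbind(new_sv_call("chr0", 0, "chr0", 1, "DEL")[0, ],
                 data.frame(n_callers = integer(0),
                            supporting_callers = character(0),
                            best_support = integer(0)))
  if (is.null(all_calls) || !nrow(all_calls)) return(empty)
  core <- c("chrom1", "pos1", "chrom2", "pos2", "sv_class", "orient1",
            "orient2", "support", "caller", "precise")
  all_calls <- all_calls[, core]
  all_calls <- canonicalize_calls(all_calls)
  all_calls <- all_calls[order(all_calls$chrom1, all_calls$pos1,
                               all_calls$chrom2, all_calls$pos2,
                               all_calls$caller), , drop = FALSE]
  rownames(all_calls) <- NULL
  n <- nrow(all_calls)

  # union-find over matching pairs
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    hits <- which(match_many(all_calls[i, ], all_calls, window))
    for (j in hits[hits > i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))

  out <- lapply(unique(comp), function(g) {
    members <- all_calls[comp == g, , drop = FALSE]
    callers <- sort(unique(members$caller))
    intra <- members$chrom1[1] == members$chrom2[1]
    need <- if (intra) min_callers_intra else min_callers_inter
    if (length(callers) < need) return(NULL)
    rep_row <- if (any(members$precise)) {
      pm <- members[members$precise, , drop = FALSE]
      pm[order(pm$caller, pm$pos1), , drop = FALSE][1, ]
    } else {
      r <- members[1, ]
      r$pos1 <- weighted_median(members$pos1, members$support)
      r$pos2 <- weighted_median(members$pos2, members$support)
      cls <- sort(table(members$sv_class), decreasing = TRUE)
      r$sv_class <- names(cls)[1]
      r
    }
    rep_row$caller <- "consensus"
    rep_row$precise <- any(members$precise)
    cbind(rep_row,
          data.frame(n_callers = length(callers),
                     supporting_callers = paste(callers, collapse = ","),
                     best_support = max(members$support),
                     stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, out)
  if (is.null(out) || !nrow(out)) return(empty)
  out <- out[order(out$chrom1, out$pos1, out$chrom2, out$pos2), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

weighted_median <- function(x, w) {
  if (all(w <= 0)) w <- rep(1, length(x))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' Remove tumor SVs present in a matched control
#'
#' Drops every tumor consensus SV matching (class requirement waived) any
#' control call with support of at least one read pair.
#'
#' @param tumor Consensus SV data.frame.
#' @param control Control SV data.frame.
#' @param window Matching window in bp.
#' @return Filtered consensus data.frame.
#' @export
subtract_germline <- function(tumor, control, window = 150) {
  if (!nrow(tumor) || is.null(control) || !nrow(control)) return(tumor)
  control <- canonicalize_calls(control[control$support >= 1, ,
                                        drop = FALSE])
  if (!nrow(control)) return(tumor)
  tumor_c <- canonicalize_calls(tumor)
  keep <- vapply(seq_len(nrow(tumor_c)), function(i) {
    !any(match_many(tumor_c[i, ], control, window, require_class = FALSE))
  }, logical(1))
  out <- tumor[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter SVs by read-pair support
#'
#' @param svs Consensus (uses `best_support`) or raw (uses `support`) SV
#'   data.frame.
#' @param min_pairs Minimum read pairs (default 3).
#' @return Filtered data.frame.
#' @export
filter_support <- function(svs, min_pairs = 3L) {
  stopifnot(min_pairs >= 0)
  if (!nrow(svs)) return(svs)
  sup <- if (!is.null(svs$best_support)) svs$best_support else svs$support
  out <- svs[sup >= min_pairs, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize SVs by class
#'
#' @param svs SV data.frame with `sv_class` (and `chrom1`), or a named
#'   count vector such as `c(DEL = 49, DUP = 25, INV = 17, TRA = 0)`.
#' @param per_chromosome Also break counts down per chromosome.
#' @return data.frame(class, n, percent, percent_int) (plus `chrom` when
#'   per-chromosome); exact percentages sum to 100, `percent_int` is
#'   rounded half-up to integers.  Empty input yields an empty table.
#' @export
summarize_by_class <- function(svs, per_chromosome = FALSE) {
  classes <- c("DEL", "DUP", "INV", "TRA")
  tab_from_counts <- function(counts, extra = NULL) {
    total <- sum(counts)
    if (total == 0) return(NULL)
    df <- data.frame(class = names(counts), n = as.integer(counts),
                     percent = 100 * as.integer(counts) / total,
                     stringsAsFactors = FALSE)
    df$percent_int <- as.integer(round_half_up(df$percent))
    if (!is.null(extra)) df <- cbind(extra, df)
    df
  }
  empty <- data.frame(class = character(0), n = integer(0),
                      percent = numeric(0), percent_int = integer(0))
  if (is.numeric(svs)) {
    counts <- svs[intersect(classes, names(svs))]
    out <- tab_from_counts(counts)
    return(out %||% empty)
  }
  if (!nrow(svs)) return(empty)
  if (per_chromosome) {
    out <- lapply(sort(unique(svs$chrom1)), function(ch) {
      counts <- table(factor(svs$sv_class[svs$chrom1 == ch], classes))
      tab_from_counts(counts, extra = data.frame(chrom = ch))
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    return(out %||% empty)
  }
  counts <- table(factor(svs$sv_class, classes))
  tab_from_counts(counts) %||% empty
}

#' Run the full harmonization chain
#'
#' consensus -> germline subtraction -> support filter, logging per-stage
#' counts.
#'
#' @param tumor_by_caller Named list of per-caller SV data.frames.
#' @param control Control SV data.frame.
#' @param window Matching window in bp.
#' @param min_callers_intra,min_callers_inter,min_support Filter settings.
#' @param verbose Print per-stage input/output counts.
#' @return Consensus SV data.frame after all filters, with per-stage counts
#'   in `attr(, "stage_counts")`.
#' @export
harmonize_sv <- function(tumor_by_caller, control, window = 150,
                         min_callers_intra = 2L, min_callers_inter = 3L,
                         min_support = 3L, verbose = FALSE) {
  n_in <- sum(vapply(tumor_by_caller, nrow, integer(1)))
  cons <- consensus(tumor_by_caller, window, min_callers_intra,
                    min_callers_inter)
  som <- subtract_germline(cons, control, window)
  out <- filter_support(som, min_support)
  counts <- c(input_calls = n_in, consensus = nrow(cons),
              somatic = nrow(som), supported = nrow(out))
  if (verbose) {
    message(paste(sprintf("%s=%d", names(counts), counts), collapse = " "))
  }
  attr(out, "stage_counts") <- counts
  out
}
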