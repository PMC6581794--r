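# Exact two-sided Fisher tests and cohort summary tables.

#' Exact two-sided Fisher test for a 2x2 table
#'
#' Enumerates every table with the observed margins; the two-sided p-value
#' sums the hypergeometric probabilities of all tables whose probability
#' does not exceed the observed table's (small-p method, the convention of
#' mainstream statistics packages), with a relative tolerance of 1e-12 for
#' floating-point ties.  Arithmetic is exact log-factorial.
#'
#' @param tab 2x2 matrix/table of non-negative counts, or the four counts
#'   a, b, c, d in row-major order.
#' @return Object of class `fisher_result`: `p_two_sided`, `odds_ratio`
#'   ((a d)/(b c) with Inf/0 conventions), `tables_enumerated`, and a
#'   `degenerate` flag (a zero margin, where p = 1 by convention).
#' @export
fisher_exact_two_sided <- function(tab) {
  x <- as.vector(t(as.matrix(tab)))
  if (length(x) != 4) stop("need a 2x2 table")
  if (any(x < 0) || any(x != round(x))) {
    stop("cell counts must be non-negative integers")
  }
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  n <- r1 + r2
  if (n == 0) stop("at least one margin must be positive")
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)

  res <- list(p_two_sided = 1, odds_ratio = or, tables_enumerated = 1L,
              degenerate = FALSE,
              table = matrix(x, 2, byrow = TRUE))
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    res$degenerate <- TRUE
    return(structure(res, class = "fisher_result"))
  }
  lo <- max(0, c1 - r2)
  hi <- min(r1, c1)
  k <- lo:hi
  logp <- lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1)
  obs <- logp[k == a]
  keep <- logp <= obs + log1p(1e-12)
  res$p_two_sided <- min(sum(exp(logp[keep])), 1)
  res$tables_enumerated <- length(k)
  structure(res, class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat(sprintf("Fisher exact test (two-sided): p = %.3f, OR = %.3g (%d tables)%s\n",
              x$p_two_sided, x$odds_ratio, x$tables_enumerated,
              if (x$degenerate) " [degenerate margin]" else ""))
  invisible(x)
}

#' Test amplification frequency between tumor groups
#'
#' Builds the 2x2 (group x amplified) table and runs
#' [fisher_exact_two_sided()].
#'
#' @param group Character vector of group labels, "early" or "late".
#' @param amplified Logical vector, one per tumor.
#' @return List: `fisher` (a `fisher_result`), `table`, and per-group
#'   amplified `fractions`.
#' @export
group_amplification_test <- function(group, amplified) {
  stopifnot(length(group) == length(amplified))
  bad <- setdiff(unique(group), c("early", "late"))
  if (length(bad)) stop("unknown group label: ", paste(bad, collapse = ", "))
  if (!all(c("early", "late") %in% group)) {
    stop("need at least one tumor per group")
  }
  g <- factor(group, c("early", "late"))
  tab <- table(g, factor(amplified, c(TRUE, FALSE)))
  res <- fisher_exact_two_sided(as.matrix(tab))
  fractions <- tapply(amplified, g, mean)
  list(fisher = res, table = as.matrix(tab), fractions = fractions)
}

#' Cohort summary with conventional rounding
#'
#' Percentage = 100 k / n, rounded half away from zero to one decimal.
#'
#' @param records data.frame with columns `k` (events) and `n` (totals) and
#'   optionally `label`, or a named list of c(k, n) pairs.
#' @return data.frame(label, k, n, percent); rows with n = 0 are dropped.
#' @export
cohort_summary <- function(records) {
  if (!is.data.frame(records)) {
    records <- do.call(rbind, lapply(names(records), function(nm) {
      data.frame(label = nm, k = records[[nm]][1], n = records[[nm]][2])
    }))
  }
  if (is.null(records$label)) records$label <- sprintf("row%d", seq_len(nrow(records)))
  records <- records[records$n > 0, , drop = FALSE]
  records$percent <- round_half_up(100 * records$k / records$n, 1)
  rownames(records) <- NULL
  records[, c("label", "k", "n", "percent")]
}
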