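# Agnostic ungapped width-7 motif discovery over 41-bp junction windows:
# ZOOPS (zero-or-one occurrence per sequence) expectation-maximization over
# both strands, seeded from the most covering 7-mers present in the data,
# with significance calibrated against dinucleotide-preserving shuffles of
# the window set.

encode_windows <- function(windows, width = 41L) {
  if (length(windows) < 2) stop("need at least 2 windows")
  if (any(nchar(windows) != width)) {
    stop("all windows must be exactly ", width, " bp")
  }
  X <- t(vapply(windows, dna_to_int, integer(width)))
  rownames(X) <- NULL
  if (any(is.na(X))) stop("windows must be uppercase ACGT")
  X
}

rc_int <- function(X) {
  Xrc <- 5L - X[, rev(seq_len(ncol(X))), drop = FALSE]
  Xrc
}

# Precompute, once per data set, everything the EM re-uses across seeds and
# iterations: per-motif-column flat base vectors over all (sequence,
# placement, strand) triples, and per-column/base index lists for the
# M-step counts.
prep_dataset <- function(X, w = 7L) {
  n <- nrow(X)
  np <- ncol(X) - w + 1L
  Xrc <- rc_int(X)
  cols <- vector("list", w)
  idx <- vector("list", w)
  for (k in seq_len(w)) {
    Bk <- cbind(X[, k:(k + np - 1L), drop = FALSE],
                Xrc[, k:(k + np - 1L), drop = FALSE])
    Bk <- as.integer(Bk)
    cols[[k]] <- Bk
    idx[[k]] <- lapply(1:4, function(b) which(Bk == b))
  }
  list(n = n, np = np, w = w, cols = cols, idx = idx)
}

# One ZOOPS EM fit from a 7-mer seed.  Background is a fixed 0-order model.
# Returns pwm, lambda, loglik trace, relative log-likelihood (vs lambda=0
# background-only model), and per-sequence site posteriors.
fit_zoops <- function(enc, seed7, bg, max_iter = 200L, tol = 1e-6,
                      seed_weight = 0.85) {
  w <- enc$w
  n <- enc$n
  np <- enc$np
  nsite <- 2L * np
  seed_int <- dna_to_int(seed7)
  pwm <- matrix((1 - seed_weight) / 3, 4, w)
  pwm[cbind(seed_int, seq_len(w))] <- seed_weight
  lambda <- 0.5
  lbg <- log(bg)
  trace <- numeric(0)
  last <- -Inf
  for (iter in seq_len(max_iter)) {
    M <- log(pwm) - lbg
    Mvec <- as.vector(M)
    s <- numeric(n * nsite)
    for (k in seq_len(w)) s <- s + Mvec[enc$cols[[k]] + 4L * (k - 1L)]
    r <- matrix(exp(s), n, nsite)
    mbar <- rowMeans(r)
    denom <- (1 - lambda) + lambda * mbar
    ll <- sum(log(denom))          # relative to background-only model
    trace <- c(trace, ll)
    z <- lambda * mbar / denom     # P(sequence has a site)
    post <- as.vector(r / pmax(rowSums(r), .Machine$double.xmin) * z)
    counts <- matrix(0, 4, w)
    for (k in seq_len(w)) {
      for (b in 1:4) counts[b, k] <- sum(post[enc$idx[[k]][[b]]])
    }
    counts <- counts + 0.5 * bg    # pseudocounts from the background
    pwm <- sweep(counts, 2, colSums(counts), "/")
    lambda <- min(max(mean(z), 1e-4), 1 - 1e-4)
    if (is.finite(last) && abs(ll - last) < tol * max(1, abs(ll))) break
    last <- ll
  }
  Mvec <- as.vector(log(pwm) - lbg)
  s <- numeric(n * nsite)
  for (k in seq_len(w)) s <- s + Mvec[enc$cols[[k]] + 4L * (k - 1L)]
  r <- matrix(exp(s), n, nsite)
  mbar <- rowMeans(r)
  denom <- (1 - lambda) + lambda * mbar
  z <- lambda * mbar / denom
  best_site <- max.col(r, ties.method = "first")
  list(pwm = pwm, lambda = lambda, llr = sum(log(denom)), trace = trace,
       z = z, best_site = best_site, np = np)
}

# Rank candidate seed 7-mers by zero-or-one-per-sequence coverage of the
# window set (a seed counts once per sequence containing it or its reverse
# complement).
rank_seeds <- function(windows, width = 7L) {
  rcw <- revcomp(windows)
  per_seq <- lapply(seq_along(windows), function(i) {
    n <- nchar(windows[i])
    starts <- seq_len(n - width + 1L)
    unique(c(substring(windows[i], starts, starts + width - 1L),
             substring(rcw[i], starts, starts + width - 1L)))
  })
  tab <- sort(table(unlist(per_seq)), decreasing = TRUE)
  # deterministic tie order: by count desc then lexicographic
  ord <- order(-as.integer(tab), names(tab))
  list(seeds = names(tab)[ord], counts = as.integer(tab)[ord],
       n_distinct = length(tab))
}

best_motif_fit <- function(windows, enc, bg, n_candidates, max_iter,
                           tol) {
  rk <- rank_seeds(windows)
  cand <- utils::head(rk$seeds, n_candidates)
  fits <- lapply(cand, function(s) fit_zoops(enc, s, bg,
                                             max_iter = max_iter,
                                             tol = tol))
  llrs <- vapply(fits, function(f) f$llr, numeric(1))
  best <- which.max(llrs)
  list(fit = fits[[best]], seed = cand[best], llr = llrs[best],
       n_seeds = rk$n_distinct)
}

# Altschul-Erickson dinucleotide-preserving shuffle of one sequence.
dinuc_shuffle <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  if (n < 3) return(seq)
  verts <- unique(ch)
  last <- ch[n]
  edges <- lapply(stats::setNames(verts, verts),
                  function(v) ch[which(ch[-n] == v) + 1L])
  for (attempt in 1:100) {
    # pick a random terminal edge for every vertex except the last symbol,
    # keep it aside, and accept if those edges form a tree into `last`
    term <- vapply(verts, function(v) {
      e <- edges[[v]]
      if (!length(e) || v == last) NA_character_ else sample(e, 1)
    }, character(1))
    ok <- TRUE
    for (v in setdiff(verts, last)) {
      cur <- v
      seen <- character(0)
      while (!is.na(term[cur])) {
        if (cur %in% seen) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- term[cur]
      }
      if (!ok || cur != last) { ok <- FALSE; break }
    }
    if (!ok) next
    shuffled <- lapply(stats::setNames(verts, verts), function(v) {
      e <- edges[[v]]
      if (is.na(term[v]) || v == last) return(sample(e))
      rest <- e[-match(term[v], e)]
      c(sample(rest), term[v])
    })
    out <- character(n)
    out[1] <- ch[1]
    ptr <- stats::setNames(rep(1L, length(verts)), verts)
    cur <- ch[1]
    for (i in 2:n) {
      nxt <- shuffled[[cur]][ptr[cur]]
      ptr[cur] <- ptr[cur] + 1L
      out[i] <- nxt
      cur <- nxt
    }
    return(paste(out, collapse = ""))
  }
  # extremely degenerate composition: fall back to the original
  seq
}

#' Discover the dominant width-7 ungapped motif in junction windows
#'
#' ZOOPS expectation-maximization over both strands.  Candidate seeds are
#' the distinct 7-mers present in the windows, ranked by
#' zero-or-one-per-sequence coverage; the top `n_candidates` are refined by
#' EM to convergence (relative log-likelihood change < `tol` or `max_iter`
#' iterations) against a 0-order background, and the best model by
#' log-likelihood ratio is kept.
#'
#' Significance: the same search is run on `n_shuffles`
#' dinucleotide-preserving shuffles of the window set.  `empirical_e` is
#' the Bonferroni-style expected number of equally good motifs in shuffled
#' data: the number of distinct candidate seeds times the Gumbel
#' (extreme-value) tail probability that a shuffled-data best LLR reaches
#' the observed one, the Gumbel fitted by moments to the shuffled best
#' LLRs.  The raw exceedance fraction is reported as `p_empirical`.
#'
#' @param windows Character vector of 41-bp sequences (>= 2).
#' @param width Motif width; fixed at 7.
#' @param n_shuffles Number of shuffled data sets for the null (default
#'   100).
#' @param seed Optional RNG seed for the shuffles.
#' @param n_candidates Seeds refined by EM (default 3).
#' @param max_iter,tol EM stopping rule.
#' @return An object of class `motif_model`: pwm (4 x 7, rows ACGT),
#'   consensus, site_count, sites, llr, empirical_e, p_empirical,
#'   shuffled_llrs, llr_trace.
#' @export
discover_motif <- function(windows, width = 7L, n_shuffles = 100L,
                           seed = NULL, n_candidates = 3L,
                           max_iter = 200L, tol = 1e-6) {
  if (width != 7L) stop("motif width is fixed at 7")
  if (!is.null(seed)) set.seed(seed)
  X <- encode_windows(windows)
  bfreq <- tabulate(X, 4) + tabulate(rc_int(X), 4)
  bg <- bfreq / sum(bfreq)

  obs <- best_motif_fit(windows, prep_dataset(X), bg, n_candidates,
                        max_iter, tol)

  shuffled <- numeric(n_shuffles)
  if (n_shuffles > 0) {
    for (s in seq_len(n_shuffles)) {
      wsh <- vapply(windows, dinuc_shuffle, character(1),
                    USE.NAMES = FALSE)
      Xs <- encode_windows(wsh)
      shuffled[s] <- best_motif_fit(wsh, prep_dataset(Xs), bg,
                                    n_candidates, max_iter, tol)$llr
    }
  }

  if (n_shuffles > 0) {
    exceed <- sum(shuffled >= obs$llr)
    p_emp <- (1 + exceed) / (1 + n_shuffles)
    beta <- stats::sd(shuffled) * sqrt(6) / pi
    if (!is.finite(beta) || beta <= 0) beta <- 1e-6
    mu <- mean(shuffled) - 0.57721566 * beta
    zshift <- (obs$llr - mu) / beta
    p_tail <- -expm1(-exp(-zshift))       # 1 - exp(-exp(-z))
    p_tail <- min(max(p_tail, 1e-300), 1)
    empirical_e <- obs$n_seeds * p_tail
  } else {
    p_emp <- NA_real_
    empirical_e <- NA_real_
  }

  fit <- obs$fit
  has_site <- fit$z >= 0.5
  np <- fit$np
  strand <- ifelse(fit$best_site > np, "-", "+")
  # the two strands carry equivalent models; canonicalize to the strand on
  # which the majority of sites lie, so a motif planted forward is
  # reported forward
  if (sum(has_site) > 0 && mean(strand[has_site] == "-") > 0.5) {
    fit$pwm <- fit$pwm[4:1, 7:1]
    rownames(fit$pwm) <- NULL
    strand <- ifelse(strand == "-", "+", "-")
  }
  consensus <- paste(DNA_BASES4[apply(fit$pwm, 2, which.max)],
                     collapse = "")
  sites <- data.frame(
    window = which(has_site),
    offset = ifelse(fit$best_site[has_site] > np,
                    fit$best_site[has_site] - np - 1L,
                    fit$best_site[has_site] - 1L),
    strand = strand[has_site],
    posterior = fit$z[has_site])
  rownames(fit$pwm) <- DNA_BASES4
  structure(list(width = width, pwm = fit$pwm,
                 site_count = sum(has_site),
                 consensus = consensus, llr = obs$llr,
                 seed = obs$seed, lambda = fit$lambda,
                 empirical_e = empirical_e, p_empirical = p_emp,
                 shuffled_llrs = shuffled, llr_trace = fit$trace,
                 sites = sites, n_candidate_seeds = obs$n_seeds),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model: consensus %s, %d sites, LLR %.2f, empirical E %.3g\n",
              x$consensus, x$site_count, x$llr, x$empirical_e))
  print(round(x$pwm, 3))
  invisible(x)
}

#' Write a motif model as a text PWM block
#'
#' @param model A `motif_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# consensus %s sites %d llr %.6f empirical_e %.6g",
                     model$consensus, model$site_count, model$llr,
                     model$empirical_e), con)
  utils::write.table(round(model$pwm, 6), con, sep = "\t", quote = FALSE,
                     col.names = FALSE)
  invisible(path)
}
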