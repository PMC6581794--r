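# Control-normalized read-depth ratios, deterministic copy-number
# segmentation, amplicon detection, SV colocalization, fold-back flagging
# and the BFB evidence score.

#' Control-normalized per-window depth ratio
#'
#' ratio = (tumor / median tumor count) / (control / median control count);
#' windows with zero control count are masked (ratio NA).
#'
#' @param windows data.frame(chrom, window_start, tumor_count,
#'   control_count).
#' @return The input with `ratio` and `masked` columns appended.
#' @export
normalize_ratio <- function(windows) {
  if (sum(windows$control_count) == 0) stop("all-zero control counts")
  med_t <- stats::median(windows$tumor_count)
  med_c <- stats::median(windows$control_count)
  if (med_t == 0) stop("median tumor count is zero")
  masked <- windows$control_count == 0
  ratio <- (windows$tumor_count / med_t) /
           (windows$control_count / med_c)
  ratio[masked] <- NA_real_
  windows$ratio <- ratio
  windows$masked <- masked
  windows
}

#' Segment per-window ratios into integer copy-number segments
#'
#' Per window, copy number = round(2 * ratio) clipped to [0, 64];
#' consecutive windows with equal copy number are merged; runs shorter than
#' `min_windows` are absorbed into the neighboring segment with the closer
#' mean ratio (ties to the left), and segment copy number is re-estimated
#' from the pooled mean ratio.  Masked windows split segments and belong to
#' none.  Deterministic.
#'
#' @param ratios Output of [normalize_ratio()] (needs chrom, window_start,
#'   ratio, masked), sorted by position within chromosome.
#' @param min_windows Minimum run length (default 3).
#' @param window_size Window size in bp.
#' @return data.frame(chrom, start, end, copy_number, mean_ratio,
#'   n_windows), non-overlapping and sorted within chromosome.
#' @export
segment_cn <- function(ratios, min_windows = 3L, window_size = 50000L) {
  out <- list()
  for (chrom in unique(ratios$chrom)) {
    sub <- ratios[ratios$chrom == chrom, , drop = FALSE]
    sub <- sub[order(sub$window_start), , drop = FALSE]
    # split into contiguous unmasked blocks
    usable <- !sub$masked
    blk <- cumsum(!usable | c(TRUE, diff(sub$window_start) != window_size))
    for (b in unique(blk[usable])) {
      w <- sub[blk == b & usable, , drop = FALSE]
      if (!nrow(w)) next
      cn <- pmin(pmax(round_half_up(2 * w$ratio), 0), 64)
      segs <- merge_cn_runs(w$window_start, w$ratio, cn, min_windows,
                            window_size)
      segs$chrom <- chrom
      out <- c(out, list(segs))
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), copy_number = integer(0),
                      mean_ratio = numeric(0), n_windows = integer(0)))
  }
  res <- res[, c("chrom", "start", "end", "copy_number", "mean_ratio",
                 "n_windows")]
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

merge_cn_runs <- function(starts, ratio, cn, min_windows, window_size) {
  r <- rle(as.vector(cn))
  lens <- r$lengths
  vals <- r$values
  idx_end <- cumsum(lens)
  idx_start <- idx_end - lens + 1L
  means <- vapply(seq_along(lens), function(i) {
    mean(ratio[idx_start[i]:idx_end[i]])
  }, numeric(1))
  # absorb short runs, shortest first, into the neighbor with closer mean
  repeat {
    if (length(lens) <= 1) break
    short <- which(lens < min_windows)
    if (!length(short)) break
    i <- short[order(lens[short], short)][1]
    left <- if (i > 1) abs(means[i] - means[i - 1]) else Inf
    right <- if (i < length(lens)) abs(means[i] - means[i + 1]) else Inf
    j <- if (left <= right) i - 1L else i + 1L
    a <- min(i, j); b <- max(i, j)
    new_len <- lens[a] + lens[b]
    new_mean <- (means[a] * lens[a] + means[b] * lens[b]) / new_len
    lens[a] <- new_len
    means[a] <- new_mean
    lens <- lens[-b]; means <- means[-b]; vals <- vals[-b]
    # merge equal-CN neighbors created by absorption
    vals_new <- pmin(pmax(round_half_up(2 * means), 0), 64)
    vals <- vals_new
    k <- 1L
    while (k < length(vals)) {
      if (vals[k] == vals[k + 1]) {
        new_len <- lens[k] + lens[k + 1]
        means[k] <- (means[k] * lens[k] + means[k + 1] * lens[k + 1]) /
          new_len
        lens[k] <- new_len
        lens <- lens[-(k + 1)]; means <- means[-(k + 1)]
        vals <- vals[-(k + 1)]
      } else k <- k + 1L
    }
  }
  idx_end <- cumsum(lens)
  idx_start <- idx_end - lens + 1L
  data.frame(start = starts[idx_start],
             end = starts[idx_end] + window_size,
             copy_number = as.integer(pmin(pmax(round_half_up(2 * means),
                                                0), 64)),
             mean_ratio = means,
             n_windows = as.integer(lens))
}

#' Detect amplified regions
#'
#' Maximal unions of segments with copy number >= `min_cn`, merged across
#' gaps up to `merge_gap`.
#'
#' @param segments Output of [segment_cn()].
#' @param min_cn Amplicon copy-number threshold (default 3).
#' @param merge_gap Maximum gap bridged, bp (default 500 kb).
#' @return data.frame(chrom, start, end), sorted.
#' @export
detect_amplicons <- function(segments, min_cn = 3L, merge_gap = 500000) {
  amp <- segments[segments$copy_number >= min_cn, , drop = FALSE]
  if (!nrow(amp)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  out <- list()
  for (chrom in unique(amp$chrom)) {
    sub <- amp[amp$chrom == chrom, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    cur_s <- sub$start[1]; cur_e <- sub$end[1]
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$start[i] - cur_e <= merge_gap) {
        cur_e <- max(cur_e, sub$end[i])
      } else {
        out <- c(out, list(data.frame(chrom = chrom, start = cur_s,
                                      end = cur_e)))
        cur_s <- sub$start[i]; cur_e <- sub$end[i]
      }
    }
    out <- c(out, list(data.frame(chrom = chrom, start = cur_s,
                                  end = cur_e)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' SVs colocalizing with a region
#'
#' Intra-chromosomal SVs require both breakpoints inside the region;
#' translocations are included with at least one breakpoint inside and
#' flagged `tra_partial`.
#'
#' @param region list/data.frame with chrom, start, end.
#' @param svs SV data.frame.
#' @return Subset of `svs` with a `tra_partial` column.
#' @export
colocalize_svs <- function(region, svs) {
  if (!nrow(svs)) {
    svs$tra_partial <- logical(0)
    return(svs)
  }
  inside <- function(chrom, pos) {
    chrom == region$chrom & pos >= region$start & pos < region$end
  }
  in1 <- inside(svs$chrom1, svs$pos1)
  in2 <- inside(svs$chrom2, svs$pos2)
  intra <- svs$sv_class != "TRA"
  keep <- (intra & in1 & in2) | (!intra & (in1 | in2))
  out <- svs[keep, , drop = FALSE]
  out$tra_partial <- !intra[keep] & !(in1[keep] & in2[keep])
  rownames(out) <- NULL
  out
}

#' Flag fold-back inversions
#'
#' Inversions whose breakpoints lie within `max_span` of each other: the SV
#' fingerprint of a BFB sister-chromatid fusion.
#'
#' @param svs SV data.frame.
#' @param max_span Maximum breakpoint distance in bp (default 5000).
#' @return List with `count` and the flagged subset `foldbacks`.
#' @export
detect_foldbacks <- function(svs, max_span = 5000) {
  if (!nrow(svs)) return(list(count = 0L, foldbacks = svs))
  fb <- svs$sv_class == "INV" & abs(svs$pos2 - svs$pos1) <= max_span
  list(count = sum(fb), foldbacks = svs[fb, , drop = FALSE])
}

#' Characterize amplicons and score BFB evidence
#'
#' For each amplified region: colocalized SVs, inversion fraction,
#' fold-back count, microhomology fraction of resolved junctions, and the
#' BFB score.
#'
#' @param segments [segment_cn()] output.
#' @param svs Consensus SV data.frame.
#' @param chemistry Optional data.frame(sv_id, chemistry, microhomology_len)
#'   for the SVs (rownames of `svs` matched through an `sv_id` column).
#' @param min_cn,merge_gap Passed to [detect_amplicons()].
#' @param max_span Passed to [detect_foldbacks()].
#' @return List of `amplicon_call` objects.
#' @export
characterize_amplicons <- function(segments, svs, chemistry = NULL,
                                   min_cn = 3L, merge_gap = 500000,
                                   max_span = 5000) {
  regions <- detect_amplicons(segments, min_cn, merge_gap)
  lapply(seq_len(nrow(regions)), function(i) {
    region <- regions[i, ]
    coloc <- colocalize_svs(region, svs)
    segs <- segments[segments$chrom == region$chrom &
                     segments$end > region$start &
                     segments$start < region$end, , drop = FALSE]
    full <- coloc[!coloc$tra_partial | coloc$sv_class != "TRA", ,
                  drop = FALSE]
    inv_frac <- if (nrow(coloc)) mean(coloc$sv_class == "INV") else 0
    fb <- detect_foldbacks(coloc, max_span)
    mh_frac <- 0
    if (!is.null(chemistry) && !is.null(coloc$sv_id)) {
      chem <- chemistry[match(coloc$sv_id, chemistry$sv_id), , drop = FALSE]
      resolved <- !is.na(chem$chemistry) & chem$chemistry != "unresolved"
      if (any(resolved)) {
        mh_frac <- mean(chem$microhomology_len[resolved] >= 1)
      }
    }
    structure(list(region = region,
                   max_copy_number = max(segs$copy_number),
                   min_copy_number = min(segs$copy_number),
                   colocalized_svs = coloc,
                   n_svs = nrow(coloc),
                   inversion_fraction = inv_frac,
                   foldback_count = fb$count,
                   mh_fraction = mh_frac),
              class = "amplicon_call")
  })
}

#' BFB evidence score
#'
#' Mean of three saturating components synthesizing the hallmarks of
#' breakage-fusion-bridge amplification: inversion predominance among
#' colocalized SVs (saturates at 50%), fold-back inversions (saturates at
#' 2), and short-homology junctions (saturates at 50%).
#'
#' @param amplicon An `amplicon_call` (or list with inversion_fraction,
#'   foldback_count, mh_fraction).
#' @return Score in [0, 1]; the components are attached as an attribute.
#' @export
bfb_score <- function(amplicon) {
  comp <- c(inversion = min(amplicon$inversion_fraction / 0.5, 1),
            foldback = min(amplicon$foldback_count / 2, 1),
            microhomology = min(amplicon$mh_fraction / 0.5, 1))
  structure(mean(comp), components = comp)
}

#' @export
print.amplicon_call <- function(x, ...) {
  s <- bfb_score(x)
  cat(sprintf("amplicon %s:%d-%d  CN %d-%d  %d SVs (inv %.0f%%, %d fold-backs, MH %.0f%%)  BFB score %.2f\n",
              x$region$chrom, x$region$start, x$region$end,
              x$min_copy_number, x$max_copy_number, x$n_svs,
              100 * x$inversion_fraction, x$foldback_count,
              100 * x$mh_fraction, s))
  invisible(x)
}

#' Write an amplicon report as TSV and JSON
#'
#' @param amplicons List of `amplicon_call` objects
#'   ([characterize_amplicons()] output).
#' @param tsv_path,json_path Output paths (either may be NULL).
#' @return The report data.frame, invisibly.
#' @export
write_amplicon_report <- function(amplicons, tsv_path = NULL,
                                  json_path = NULL) {
  rows <- lapply(amplicons, function(a) {
    data.frame(chrom = a$region$chrom, start = a$region$start,
               end = a$region$end, max_copy_number = a$max_copy_number,
               min_copy_number = a$min_copy_number, n_svs = a$n_svs,
               inversion_fraction = a$inversion_fraction,
               foldback_count = a$foldback_count,
               mh_fraction = a$mh_fraction,
               bfb_score = as.numeric(bfb_score(a)),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  if (!is.null(tsv_path)) {
    utils::write.table(report, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, digits = NA, pretty = TRUE)
  }
  invisible(report)
}

#' Write copy-number segments as BED
#'
#' @param segments [segment_cn()] output.
#' @param path Output path (chrom, start, end, name = CN,
#'   score = mean ratio x 100).
#' @return `path`, invisibly.
#' @export
write_segments_bed <- function(segments, path) {
  df <- data.frame(segments$chrom, segments$start, segments$end,
                   paste0("CN", segments$copy_number),
                   round(segments$mean_ratio * 100))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
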