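# Breakpoint-junction sequence analysis: 41-bp windows, cryptic RSS
# scanning, V(D)J joint typing, and microhomology/insertion chemistry.

#' Construct a junction record
#'
#' A junction record carries the consensus sequence spanning a breakpoint
#' join together with orientation-adjusted 20-bp reference contexts: the
#' flank ending at the join on each side, plus the reference continuation
#' past the join on the left side (`cont_left`) and the reference context
#' preceding the join on the right side (`pre_right`), both read
#' left-to-right in junction orientation (inversion joins are
#' reverse-complemented).  `window41` is the 41-bp window centered on the
#' join: 20 bp left, the first joined base, 20 bp right.
#'
#' @param sv_id Identifier linking back to a consensus SV.
#' @param junction_seq Consensus sequence across the join.
#' @param flank_left,cont_left,pre_right,flank_right 20-bp reference
#'   contexts as described above.
#' @param join Number of left-derived bases in `junction_seq`.
#' @return An object of class `junction_record`.
#' @export
junction_record <- function(sv_id, junction_seq, flank_left, cont_left,
                            pre_right, flank_right, join) {
  stopifnot(nchar(flank_left) == 20, nchar(flank_right) == 20)
  if (join < 20 || nchar(junction_seq) - join < 21) {
    stop("consensus sequence must span the join by >= 20 bp each side")
  }
  window41 <- substr(junction_seq, join - 19L, join + 21L)
  structure(list(sv_id = sv_id, junction_seq = junction_seq,
                 left_flank_ref = flank_left, right_flank_ref = flank_right,
                 cont_left = cont_left, pre_right = pre_right,
                 join = as.integer(join), window41 = window41),
            class = "junction_record")
}

#' Extract junction windows for a precisely resolved SV
#'
#' Pulls the orientation-adjusted 20-bp reference flanks for both
#' breakpoints from the genome and anchors the consensus sequence at the
#' join by locating the left flank within it (exact match first, else the
#' best sliding alignment at >= 15/20 identity).
#'
#' @param sv One-row SV data.frame (consensus or call) with columns chrom1,
#'   pos1, chrom2, pos2, sv_class, precise.
#' @param genome A `toy_genome` (or any list with a `chromosomes` field).
#' @param consensus_seq Consensus sequence spanning the join by >= 20 bp on
#'   each side.
#' @param sv_id Identifier stored in the record.
#' @return A `junction_record`, or NULL (with a warning) for an imprecise SV.
#' @export
extract_junction_windows <- function(sv, genome, consensus_seq,
                                     sv_id = "sv") {
  if (!isTRUE(sv$precise)) {
    warning("skipping imprecise SV ", sv_id)
    return(NULL)
  }
  if (nchar(consensus_seq) < 41) {
    stop("consensus sequence shorter than 41 bp for ", sv_id)
  }
  s <- junction_sides(sv)
  lenL <- nchar(genome$chromosomes[[s$left$chrom]])
  lenR <- nchar(genome$chromosomes[[s$right$chrom]])
  if (s$left$pos < 20 || s$left$pos > lenL - 20 ||
      s$right$pos < 20 || s$right$pos > lenR - 20) {
    stop("breakpoint within 20 bp of a chromosome end for ", sv_id)
  }
  ctx <- junction_context(genome, sv)
  anchor <- anchor_sequence(consensus_seq, ctx$flank_left,
                            from_left = TRUE)
  if (is.null(anchor)) {
    stop("consensus sequence does not anchor to the left flank for ", sv_id)
  }
  join <- anchor$end
  junction_record(sv_id, consensus_seq, ctx$flank_left, ctx$cont_left,
                  ctx$pre_right, ctx$flank_right, join)
}

# Locate a 20-mer inside a longer sequence.  Exact match preferred (first
# occurrence from the chosen side); otherwise best sliding-window identity,
# requiring >= min_ident matches.  Returns list(start, end, ident) in
# 1-based coordinates of `seq`, or NULL.
anchor_sequence <- function(seq, probe, from_left = TRUE, min_ident = 15L) {
  w <- nchar(probe)
  n <- nchar(seq)
  if (n < w) return(NULL)
  hit <- if (from_left) regexpr(probe, seq, fixed = TRUE)
         else {
           g <- gregexpr(probe, seq, fixed = TRUE)[[1]]
           if (g[1] == -1) -1L else g[length(g)]
         }
  if (hit != -1) {
    return(list(start = as.integer(hit), end = as.integer(hit) + w - 1L,
                ident = w))
  }
  pchars <- strsplit(probe, "")[[1]]
  starts <- seq_len(n - w + 1L)
  ident <- vapply(starts, function(s) {
    sum(strsplit(substr(seq, s, s + w - 1L), "")[[1]] == pchars)
  }, integer(1))
  best <- if (from_left) which.max(ident) else {
    mx <- max(ident); max(which(ident == mx))
  }
  if (ident[best] < min_ident) return(NULL)
  list(start = starts[best], end = starts[best] + w - 1L,
       ident = ident[best])
}

# Longest run of agreement between two character strings starting at
# position 1 (prefix) or aligned at their ends (suffix).
match_forward <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- strsplit(substr(a, 1, n), "")[[1]]
  bv <- strsplit(substr(b, 1, n), "")[[1]]
  neq <- which(av != bv)
  if (!length(neq)) n else neq[1] - 1L
}

match_backward <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0) return(0L)
  av <- rev(strsplit(a, "")[[1]])[seq_len(n)]
  bv <- rev(strsplit(b, "")[[1]])[seq_len(n)]
  neq <- which(av != bv)
  if (!length(neq)) n else neq[1] - 1L
}

# Maximal-extension attribution of a junction sequence to its two reference
# sides.  Anchors the left flank (leftmost occurrence) and right flank
# (rightmost occurrence), extends the left anchor forward along cont_left
# and the right anchor backward along pre_right, and reads off the overlap
# (microhomology) or gap (non-templated insertion).
attribute_junction <- function(junction, flank_left, cont_left,
                               pre_right, flank_right) {
  aL <- anchor_sequence(junction, flank_left, from_left = TRUE)
  aR <- anchor_sequence(junction, flank_right, from_left = FALSE)
  if (is.null(aL) || is.null(aR) || aR$start <= aL$start) {
    return(list(chemistry = "unresolved", microhomology_len = 0L,
                inserted_bases = "", join = NA_integer_))
  }
  j <- aL$end                       # last left-attributed base (1-based)
  r_start <- aR$start               # first right-attributed base
  a <- match_forward(substr(junction, j + 1L, nchar(junction)), cont_left)
  b <- match_backward(substr(junction, 1L, r_start - 1L), pre_right)
  L_reach <- j + a
  R_reach <- r_start - b
  if (L_reach >= R_reach - 1L) {
    overlap <- L_reach - R_reach + 1L
    list(chemistry = if (overlap > 0) "microhomology" else "blunt",
         microhomology_len = as.integer(max(overlap, 0L)),
         inserted_bases = "", join = j)
  } else {
    list(chemistry = "insertion", microhomology_len = 0L,
         inserted_bases = substr(junction, L_reach + 1L, R_reach - 1L),
         join = j)
  }
}

#' Call breakpoint-junction chemistry
#'
#' Classifies a junction as blunt, microhomology (with length) or
#' non-templated insertion (with the inserted bases) by maximal-extension
#' attribution of the consensus sequence to the two reference sides.
#' Junction bases attributable to both flank continuations form the
#' microhomology block; bases attributable to neither are the insertion.
#' Ties favor microhomology (maximal-overlap convention); insertion is
#' called only when unmatched bases remain under every attribution.  A
#' junction that fails to anchor to either flank at >= 15/20 identity is
#' returned as "unresolved".
#'
#' @param rec A [junction_record()].
#' @return List with `chemistry`, `microhomology_len`, `inserted_bases`.
#' @export
call_chemistry <- function(rec) {
  att <- attribute_junction(rec$junction_seq, rec$left_flank_ref,
                            rec$cont_left, rec$pre_right,
                            rec$right_flank_ref)
  att[c("chemistry", "microhomology_len", "inserted_bases")]
}

#' Scan a sequence for cryptic RSS heptamer matches
#'
#' Both orientations are scanned.  A CAC-orientation hit is a 7-mer with an
#' exact CAC anchor at its start; a GTG-orientation hit ends in GTG (its
#' reverse complement starts CAC).  The score counts matches to the
#' canonical heptamer CACAGTG over positions 4-7 (the AGTG tail), 0-4, with
#' the anchor required exactly.  Where a 7-mer qualifies in both
#' orientations the higher-scoring one is reported (CAC on ties).
#'
#' @param seq Uppercase ACGT string.
#' @param min_score Minimum tail score to report (default 2, consistent
#'   with the degenerate consensus CAC(A/C)(C/G)(A/T)(G/C)).
#' @return data.frame(offset, orientation, matched7, score), offsets
#'   0-based, sorted by offset.
#' @export
scan_crss <- function(seq, min_score = 2L) {
  n <- nchar(seq)
  empty <- data.frame(offset = integer(0), orientation = character(0),
                      matched7 = character(0), score = integer(0),
                      stringsAsFactors = FALSE)
  if (n < 7) return(empty)
  starts <- seq_len(n - 6L)
  kmers <- substring(seq, starts, starts + 6L)
  tail_score <- function(k7) {
    sum(strsplit(substr(k7, 4, 7), "")[[1]] ==
        c("A", "G", "T", "G"))
  }
  out <- lapply(seq_along(kmers), function(i) {
    k <- kmers[i]
    fwd_ok <- startsWith(k, "CAC")
    rc <- revcomp(k)
    rev_ok <- startsWith(rc, "CAC")   # equivalently k ends with GTG
    if (!fwd_ok && !rev_ok) return(NULL)
    sf <- if (fwd_ok) tail_score(k) else -1L
    sr <- if (rev_ok) tail_score(rc) else -1L
    # report the better orientation; an exact tie (near-palindromic
    # heptamer) is genuinely ambiguous and is reported in both
    rows <- list()
    if (sf >= sr) {
      rows <- c(rows, list(data.frame(offset = starts[i] - 1L,
                                      orientation = "CAC", matched7 = k,
                                      score = as.integer(sf),
                                      stringsAsFactors = FALSE)))
    }
    if (sr >= sf) {
      rows <- c(rows, list(data.frame(offset = starts[i] - 1L,
                                      orientation = "GTG", matched7 = k,
                                      score = as.integer(sr),
                                      stringsAsFactors = FALSE)))
    }
    do.call(rbind, rows)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  out <- out[out$score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$offset), , drop = FALSE]
}

#' Classify a breakpoint junction as a V(D)J-type joint
#'
#' Implements RAG-consistency orientation logic on the reference: the
#' 41-bp reference window of breakpoint 1 must contain a CAC-orientation
#' heptamer whose anchor begins at, or within `anchor_tol` bp right of, the
#' breakpoint, and the window of breakpoint 2 a GTG-orientation heptamer
#' ending at, or within `anchor_tol` bp left of, the breakpoint (resection
#' shifts apparent breakpoints outward, so the tolerance absorbs geometric
#' resection).  Heptamer inclusion in the junction is then tested with a
#' 14-bp probe (heptamer plus its 7 bp of distal reference context, which
#' disambiguates the two RSS copies): both excluded = coding joint, both
#' included = signal joint, exactly one included = hybrid joint; a failed
#' orientation test yields "none".
#'
#' @param rec A [junction_record()].
#' @param sv The one-row SV data.frame the record belongs to.
#' @param genome A `toy_genome`.
#' @param min_score Minimum heptamer tail score (default 4: the perfect
#'   CACAGTG used for canonical V(D)J typing; lower to 2 for degenerate
#'   cryptic RSS searches).
#' @param anchor_tol Breakpoint-to-anchor tolerance in bp (default 10).
#' @return List: `joint_type` (coding/signal/hybrid/none), `rss_left`,
#'   `rss_right` (hit rows or NULL), plus the chemistry fields of
#'   [call_chemistry()].
#' @export
classify_vdj_junction <- function(rec, sv, genome, min_score = 4L,
                                  anchor_tol = 10L) {
  chem <- call_chemistry(rec)
  none <- c(list(sv_id = rec$sv_id, joint_type = "none",
                 rss_left = NULL, rss_right = NULL), chem)
  p1 <- sv$pos1; p2 <- sv$pos2
  c1 <- sv$chrom1; c2 <- sv$chrom2
  len1 <- nchar(genome$chromosomes[[c1]])
  len2 <- nchar(genome$chromosomes[[c2]])
  if (p1 < 20 || p1 > len1 - 21 || p2 < 20 || p2 > len2 - 21) return(none)
  w1 <- genome_seq(genome, c1, p1 - 20L, p1 + 21L)
  w2 <- genome_seq(genome, c2, p2 - 20L, p2 + 21L)

  h1 <- scan_crss(w1, min_score = min_score)
  h1 <- h1[h1$orientation == "CAC" & h1$offset >= 20 &
           h1$offset <= 20 + anchor_tol, , drop = FALSE]
  h2 <- scan_crss(w2, min_score = min_score)
  # window index 20 is the breakpoint base, so a heptamer ending exactly at
  # the breakpoint has offset + 7 == 20; resection shifts it left
  h2 <- h2[h2$orientation == "GTG" & h2$offset + 7 <= 20 &
           h2$offset + 7 >= 20 - anchor_tol, , drop = FALSE]
  if (!nrow(h1) || !nrow(h2)) return(none)
  h1 <- h1[order(-h1$score, h1$offset), , drop = FALSE][1, ]
  h2 <- h2[order(-h2$score, -h2$offset), , drop = FALSE][1, ]

  # inclusion probes: heptamer + 7 bp distal context, in the reference
  a1 <- p1 + (h1$offset - 20L)            # heptamer start on chrom1
  e2 <- p2 + (h2$offset + 7L - 20L)       # heptamer end on chrom2
  probe1 <- genome_seq(genome, c1, a1, min(a1 + 14L, len1))
  probe2 <- genome_seq(genome, c2, max(e2 - 14L, 0L), e2)
  inc1 <- probe_included(rec, probe1)
  inc2 <- probe_included(rec, probe2)

  joint <- if (!inc1 && !inc2) "coding"
           else if (inc1 && inc2) "signal"
           else "hybrid"
  c(list(sv_id = rec$sv_id, joint_type = joint,
         rss_left = h1, rss_right = h2), chem)
}

# A heptamer (with context) is "included" if the probe or its reverse
# complement occurs in the junction sequence overlapping the +-24 bp zone
# around the join.
probe_included <- function(rec, probe, zone = 24L) {
  j <- rec$join
  for (p in c(probe, revcomp(probe))) {
    g <- gregexpr(p, rec$junction_seq, fixed = TRUE)[[1]]
    if (g[1] == -1) next
    for (s in g) {
      if (s <= j + zone && s + nchar(p) - 1L >= j - zone + 1L) return(TRUE)
    }
  }
  FALSE
}

#' Tabulate junction types by group
#'
#' @param calls List of classification results ([classify_vdj_junction()]
#'   output) or a data.frame with columns `joint_type` and `chemistry`.
#' @param groups Group label per call.
#' @return data.frame of per-group fractions for chemistry
#'   (insertion/microhomology/blunt) and joint type
#'   (coding/signal/hybrid/none); fractions per group sum to 1.  Empty
#'   groups are dropped with a warning.
#' @export
junction_type_table <- function(calls, groups) {
  if (is.data.frame(calls)) {
    df <- calls
  } else {
    df <- data.frame(
      joint_type = vapply(calls, function(x) x$joint_type %||% NA_character_,
                          character(1)),
      chemistry = vapply(calls, function(x) x$chemistry, character(1)),
      stringsAsFactors = FALSE)
  }
  stopifnot(length(groups) == nrow(df))
  out <- list()
  for (g in unique(groups)) {
    sub <- df[groups == g, , drop = FALSE]
    sub <- sub[sub$chemistry != "unresolved", , drop = FALSE]
    if (!nrow(sub)) {
      warning("group '", g, "' has no resolved junctions; omitted")
      next
    }
    n <- nrow(sub)
    chem_levels <- c("insertion", "microhomology", "blunt")
    joint_levels <- c("coding", "signal", "hybrid", "none")
    chem_f <- as.vector(table(factor(sub$chemistry, chem_levels))) / n
    joint_f <- as.vector(table(factor(sub$joint_type, joint_levels))) / n
    out[[g]] <- data.frame(group = g, n = n,
                           t(stats::setNames(chem_f, chem_levels)),
                           t(stats::setNames(joint_f, joint_levels)),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (!is.null(res)) rownames(res) <- NULL
  res
}
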