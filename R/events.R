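# Simulated rearrangement events with defined breakpoint-junction chemistry.
#
# Coordinate convention: 0-based half-open everywhere.  A junction is
# left-part + (inserted bases) + right-part, where the parts are read
# left-to-right across the join.  Per SV class the parts come from:
#   DEL  left = G[pos1-f, pos1)          right = G[pos2, pos2+f)
#   TRA  left = G1[pos1-f, pos1)         right = G2[pos2, pos2+f)
#   DUP  left = G[pos2-f, pos2)          right = G[pos1, pos1+f)
#   INV  left = G[pos1-f, pos1)          right = revcomp(G[pos2-f, pos2))
# (f = 30 bp in emitted consensus sequences).
#
# Planted microhomology of length m means the junction bases adjacent to the
# join are attributable to BOTH reference sides; it is written into the
# genome by copying m bases so the attribution is exact.  One base beyond
# every planted boundary is forced to mismatch (at a position that is never
# inside a planted heptamer) so that the recorded truth chemistry is the
# unique maximal-overlap attribution of the junction -- the same convention
# the chemistry caller uses.

JUNCTION_FLANK <- 30L

new_sv_call <- function(chrom1, pos1, chrom2, pos2, sv_class,
                        orient1 = "+", orient2 = "+",
                        support = 0L, caller = "truth", precise = TRUE) {
  if (chrom1 == chrom2 && pos1 > pos2) {
    tmp <- pos1; pos1 <- pos2; pos2 <- tmp
  }
  if ((sv_class == "TRA") != (chrom1 != chrom2)) {
    stop("sv_class TRA iff chrom1 != chrom2 (got ", sv_class, " on ",
         chrom1, "/", chrom2, ")")
  }
  data.frame(chrom1 = chrom1, pos1 = as.integer(pos1),
             chrom2 = chrom2, pos2 = as.integer(pos2),
             sv_class = sv_class, orient1 = orient1, orient2 = orient2,
             support = as.integer(support), caller = caller,
             precise = precise, stringsAsFactors = FALSE)
}

# Replace the base at `pos` if it is in `forbidden` (all safe call sites are
# background sequence, never inside a planted heptamer or homology tract).
enforce_base <- function(genome, chrom, pos, forbidden) {
  cur <- genome_seq(genome, chrom, pos, pos + 1L)
  if (cur %in% forbidden) {
    choices <- setdiff(DNA_BASES4, unique(c(forbidden, cur)))
    genome <- genome_edit(genome, chrom, pos, sample(choices, 1L))
  }
  genome
}

random_insert <- function(len, first_not = character(0),
                          last_not = character(0)) {
  repeat {
    ins <- strsplit(rand_dna(len), "")[[1]]
    if (!(ins[1] %in% first_not) && !(ins[len] %in% last_not)) {
      return(paste(ins, collapse = ""))
    }
  }
}

draw_chemistry <- function(config, ins_fraction) {
  if (stats::runif(1) < ins_fraction) {
    list(type = "insertion", m = 0L,
         ins_len = sample.int(10L, 1L))
  } else if (stats::runif(1) < config$mh_fraction_no_insertion) {
    list(type = "microhomology",
         m = sample.int(config$microhomology_max, 1L), ins_len = 0L)
  } else {
    list(type = "blunt", m = 0L, ins_len = 0L)
  }
}

rgeom_mean <- function(n, mean) {
  if (mean <= 0) return(integer(n))
  stats::rgeom(n, prob = 1 / (1 + mean))
}

# Junction part sources for one SV, in junction orientation.  Each side is
# list(chrom, pos, rc): a non-rc left part reads forward and ends at pos; an
# rc left part is revcomp(G[pos, pos+f)) (approaches pos from above).  A
# non-rc right part reads forward from pos; an rc right part is
# revcomp(G[pos-f, pos)).  Inversions have two junction types: orient1 "+"
# is the head-to-head join at the high side (left forward into the inverted
# segment read back), orient1 "-" the tail-to-tail join at the low side.
junction_sides <- function(sv) {
  switch(sv$sv_class,
    DEL = ,
    TRA = list(left = list(chrom = sv$chrom1, pos = sv$pos1, rc = FALSE),
               right = list(chrom = sv$chrom2, pos = sv$pos2, rc = FALSE)),
    DUP = list(left = list(chrom = sv$chrom1, pos = sv$pos2, rc = FALSE),
               right = list(chrom = sv$chrom2, pos = sv$pos1, rc = FALSE)),
    INV = if (sv$orient1 == "+") {
      list(left = list(chrom = sv$chrom1, pos = sv$pos1, rc = FALSE),
           right = list(chrom = sv$chrom2, pos = sv$pos2, rc = TRUE))
    } else {
      list(left = list(chrom = sv$chrom1, pos = sv$pos2, rc = TRUE),
           right = list(chrom = sv$chrom2, pos = sv$pos1, rc = FALSE))
    },
    stop("unknown sv_class ", sv$sv_class))
}

side_left_seq <- function(genome, side, f) {
  if (!side$rc) genome_seq(genome, side$chrom, side$pos - f, side$pos)
  else revcomp(genome_seq(genome, side$chrom, side$pos, side$pos + f))
}

side_right_seq <- function(genome, side, f) {
  if (!side$rc) genome_seq(genome, side$chrom, side$pos, side$pos + f)
  else revcomp(genome_seq(genome, side$chrom, side$pos - f, side$pos))
}

# Reference context strings (20 bp) for chemistry attribution.
junction_context <- function(genome, sv, f = 20L) {
  s <- junction_sides(sv)
  contL <- if (!s$left$rc) {
    genome_seq(genome, s$left$chrom, s$left$pos, s$left$pos + f)
  } else {
    revcomp(genome_seq(genome, s$left$chrom, s$left$pos - f, s$left$pos))
  }
  preR <- if (!s$right$rc) {
    genome_seq(genome, s$right$chrom, s$right$pos - f, s$right$pos)
  } else {
    revcomp(genome_seq(genome, s$right$chrom, s$right$pos,
                       s$right$pos + f))
  }
  list(flank_left = side_left_seq(genome, s$left, f),
       cont_left = contL,
       pre_right = preR,
       flank_right = side_right_seq(genome, s$right, f))
}

build_junction_seq <- function(genome, sv, mid = "") {
  s <- junction_sides(sv)
  f <- JUNCTION_FLANK
  paste0(side_left_seq(genome, s$left, f), mid,
         side_right_seq(genome, s$right, f))
}

# Plant chemistry into the genome for one SV and return the (possibly
# edited) genome plus the inserted bases.  `pinned1`/`pinned2` say whether a
# planted heptamer sits against breakpoint 1 / 2 (RSS geometry: heptamer
# right of pos1 in CAC orientation, heptamer left of pos2 ending at pos2).
plant_chemistry <- function(genome, sv, chem, pinned1 = FALSE,
                            pinned2 = FALSE) {
  m <- chem$m
  ins <- ""
  c1 <- sv$chrom1; c2 <- sv$chrom2
  p1 <- sv$pos1; p2 <- sv$pos2
  base <- function(chrom, pos) genome_seq(genome, chrom, pos, pos + 1L)

  if (sv$sv_class %in% c("DEL", "TRA")) {
    if (chem$type == "microhomology") {
      genome <- genome_edit(genome, c2, p2,
                            genome_seq(genome, c1, p1, p1 + m))
      genome <- enforce_base(genome, c2, p2 + m, base(c1, p1 + m))
      genome <- enforce_base(genome, c1, p1 - 1L, base(c2, p2 - 1L))
    } else if (chem$type == "insertion") {
      ins <- random_insert(chem$ins_len, first_not = base(c1, p1),
                           last_not = base(c2, p2 - 1L))
    } else {
      genome <- enforce_base(genome, c2, p2, base(c1, p1))
      genome <- enforce_base(genome, c1, p1 - 1L, base(c2, p2 - 1L))
    }
  } else if (sv$sv_class == "DUP") {
    if (chem$type == "microhomology") {
      genome <- genome_edit(genome, c1, p1 - m,
                            genome_seq(genome, c1, p2 - m, p2))
      genome <- enforce_base(genome, c1, p1 - m - 1L, base(c1, p2 - m - 1L))
      genome <- enforce_base(genome, c1, p2, base(c1, p1))
    } else if (chem$type == "insertion") {
      ins <- random_insert(chem$ins_len, first_not = base(c1, p2),
                           last_not = base(c1, p1 - 1L))
    } else {
      genome <- enforce_base(genome, c1, p2, base(c1, p1))
      genome <- enforce_base(genome, c1, p1 - 1L, base(c1, p2 - 1L))
    }
  } else if (sv$sv_class == "INV" && sv$orient1 == "-") {
    # tail-to-tail junction: revcomp(G[p2, p2+f)) + G[p1, p1+f)
    if (chem$type == "microhomology") {
      genome <- genome_edit(genome, c1, p1,
                            revcomp(genome_seq(genome, c1, p2 - m, p2)))
      genome <- enforce_base(genome, c1, p2 - m - 1L,
                             revcomp(base(c1, p1 + m)))
      genome <- enforce_base(genome, c1, p1 - 1L, revcomp(base(c1, p2)))
    } else if (chem$type == "insertion") {
      ins <- random_insert(chem$ins_len,
                           first_not = revcomp(base(c1, p2 - 1L)),
                           last_not = base(c1, p1 - 1L))
    } else {
      genome <- enforce_base(genome, c1, p2 - 1L, revcomp(base(c1, p1)))
      genome <- enforce_base(genome, c1, p1 - 1L, revcomp(base(c1, p2)))
    }
  } else if (sv$sv_class == "INV") {
    if (chem$type == "microhomology") {
      genome <- genome_edit(genome, c1, p2,
                            revcomp(genome_seq(genome, c1, p1 - m, p1)))
      genome <- enforce_base(genome, c1, p2 + m,
                             revcomp(base(c1, p1 - m - 1L)))
      if (!pinned2) {
        genome <- enforce_base(genome, c1, p2 - 1L,
                               revcomp(base(c1, p1)))
      } else if (!pinned1) {
        genome <- enforce_base(genome, c1, p1, revcomp(base(c1, p2 - 1L)))
      }  # both pinned: CAC/CAC ambiguity is inherent, recorded as measured
    } else if (chem$type == "insertion") {
      ins <- random_insert(chem$ins_len, first_not = base(c1, p1),
                           last_not = revcomp(base(c1, p2)))
    } else {
      genome <- enforce_base(genome, c1, p2, revcomp(base(c1, p1 - 1L)))
      if (!pinned2) {
        genome <- enforce_base(genome, c1, p2 - 1L, revcomp(base(c1, p1)))
      } else if (!pinned1) {
        genome <- enforce_base(genome, c1, p1, revcomp(base(c1, p2 - 1L)))
      }
    }
  }
  list(genome = genome, ins = ins)
}

new_sv_truth <- function(genome, sv, ins, rss_left = NA_integer_,
                         rss_right = NA_integer_,
                         vdj_joint_type = NA_character_,
                         germline = FALSE) {
  jseq <- build_junction_seq(genome, sv, mid = ins)
  ctx <- junction_context(genome, sv)
  att <- attribute_junction(jseq, ctx$flank_left, ctx$cont_left,
                            ctx$pre_right, ctx$flank_right)
  structure(list(sv = sv,
                 junction_sequence = jseq,
                 join = JUNCTION_FLANK,
                 chemistry = att$chemistry,
                 microhomology_len = att$microhomology_len,
                 inserted_bases = att$inserted_bases,
                 context = ctx,
                 rss_left = rss_left, rss_right = rss_right,
                 vdj_joint_type = vdj_joint_type,
                 germline = germline),
            class = "sv_truth")
}

#' @export
print.sv_truth <- function(x, ...) {
  cat(sprintf("sv_truth %s %s:%d -- %s:%d  chemistry=%s(mh=%d, ins='%s')%s\n",
              x$sv$sv_class, x$sv$chrom1, x$sv$pos1, x$sv$chrom2, x$sv$pos2,
              x$chemistry, x$microhomology_len, x$inserted_bases,
              if (!is.na(x$vdj_joint_type)) paste0(" joint=", x$vdj_joint_type)
              else ""))
  invisible(x)
}

#' Simulate one canonical V(D)J recombination event
#'
#' Two convergent canonical heptamers on one chromosome define a deletion:
#' the coding joint excludes both heptamers, suffers independent geometric
#' resection of each coding end, and carries a 1-10 bp non-templated
#' insertion with probability `config$insertion_fraction_vdj`; the reciprocal
#' signal joint fuses the two heptamer ends head-to-head, blunt and
#' unresected.  A hybrid joint (one coding end joined to the other RSS end,
#' one heptamer retained) can be requested instead for classifier fixtures.
#'
#' @param genome A `toy_genome`.
#' @param rss_pair Two-row subset of `genome$planted_rss`: one "+" and one
#'   "-" canonical planting on the same chromosome, "+" upstream.
#' @param config A [sim_config()].
#' @param emit Character vector from c("coding", "signal", "hybrid").
#' @return List with `truths` (list of `sv_truth`) and the updated `genome`.
#' @export
simulate_vdj_event <- function(genome, rss_pair, config,
                               emit = c("coding", "signal")) {
  emit <- match.arg(emit, c("coding", "signal", "hybrid"),
                    several.ok = TRUE)
  if (nrow(rss_pair) != 2) stop("rss_pair must have exactly two sites")
  if (!all(rss_pair$is_canonical)) {
    stop("both RSS sites must be canonical for a V(D)J event")
  }
  if (length(unique(rss_pair$chrom)) != 1) {
    stop("canonical V(D)J events are intra-chromosomal: sites on different chromosomes")
  }
  fwd <- rss_pair[rss_pair$orientation == "+", , drop = FALSE]
  rev <- rss_pair[rss_pair$orientation == "-", , drop = FALSE]
  if (nrow(fwd) != 1 || nrow(rev) != 1 || fwd$offset >= rev$offset) {
    stop("rss_pair must be convergent: one '+' site upstream of one '-' site")
  }
  chrom <- fwd$chrom
  p1 <- fwd$offset          # heptamer occupies [p1, p1+7) in CAC orientation
  p2 <- rev$offset + 7L     # heptamer occupies [p2-7, p2), GTG at its end
  base <- function(pos) genome_seq(genome, chrom, pos, pos + 1L)
  truths <- list()

  if ("coding" %in% emit) {
    r <- rgeom_mean(2L, config$resection_mean)
    lp <- p1 - r[1]; rp <- p2 + r[2]
    sv <- new_sv_call(chrom, lp, chrom, rp, "DEL")
    ins_draw <- stats::runif(1) < config$insertion_fraction_vdj
    if (ins_draw) {
      len <- sample.int(10L, 1L)
      ins <- random_insert(len, first_not = base(lp), last_not = base(rp - 1L))
    } else {
      ins <- ""
      genome <- enforce_base(genome, chrom, rp, base(lp))
      genome <- enforce_base(genome, chrom, lp - 1L, base(rp - 1L))
    }
    truths <- c(truths, list(new_sv_truth(genome, sv, ins,
                                          rss_left = fwd$offset,
                                          rss_right = rev$offset,
                                          vdj_joint_type = "coding")))
  }
  if ("signal" %in% emit) {
    # reciprocal joint on the excised circle: heptamer ends fused blunt,
    # junction reads ...CACTGTG | CACAGTG...
    sv <- new_sv_call(chrom, p1, chrom, p2, "DUP", orient1 = "-",
                      orient2 = "-")
    genome <- enforce_base(genome, chrom, p2, base(p1))
    genome <- enforce_base(genome, chrom, p1 - 1L, base(p2 - 1L))
    truths <- c(truths, list(new_sv_truth(genome, sv, "",
                                          rss_left = fwd$offset,
                                          rss_right = rev$offset,
                                          vdj_joint_type = "signal")))
  }
  if ("hybrid" %in% emit) {
    r1 <- rgeom_mean(1L, config$resection_mean)
    lp <- p1 - r1
    sv <- new_sv_call(chrom, lp, chrom, p2, "INV", orient1 = "+",
                      orient2 = "-")
    ins_draw <- stats::runif(1) < config$insertion_fraction_vdj
    if (ins_draw) {
      len <- sample.int(10L, 1L)
      ins <- random_insert(len, first_not = base(lp),
                           last_not = revcomp(base(p2)))
    } else {
      ins <- ""
      if (lp < p1) genome <- enforce_base(genome, chrom, lp,
                                          revcomp(base(p2 - 1L)))
      genome <- enforce_base(genome, chrom, p2, revcomp(base(lp - 1L)))
    }
    truths <- c(truths, list(new_sv_truth(genome, sv, ins,
                                          rss_left = fwd$offset,
                                          rss_right = rev$offset,
                                          vdj_joint_type = "hybrid")))
  }
  list(truths = truths, genome = genome)
}

# Pick an unused planted cryptic site of the requested orientation.
take_cryptic_site <- function(genome, orientation, chrom = NULL,
                              min_pos = -Inf, max_pos = Inf,
                              prev_base_not = NULL) {
  df <- genome$planted_rss
  ok <- !df$used & !df$is_canonical & df$orientation == orientation
  if (!is.null(chrom)) ok <- ok & df$chrom == chrom
  ok <- ok & df$offset > min_pos & df$offset < max_pos
  idx <- which(ok)
  if (!is.null(prev_base_not) && length(idx)) {
    pre <- vapply(idx, function(i) {
      genome_seq(genome, df$chrom[i], df$offset[i] - 1L, df$offset[i])
    }, character(1))
    idx <- idx[pre != prev_base_not]
  }
  if (!length(idx)) return(NULL)
  sample(idx, 1L)
}

# Random breakpoint away from plantings and previously used breakpoints.
random_breakpoint <- function(genome, chrom, min_pos = NULL, max_pos = NULL) {
  L <- nchar(genome$chromosomes[[chrom]])
  lo <- max(1050L, min_pos %||% 1050L)
  hi <- min(L - 1050L, max_pos %||% (L - 1050L))
  if (hi <= lo) stop("chromosome ", chrom, " too short for a breakpoint")
  planted <- genome$planted_rss$offset[genome$planted_rss$chrom == chrom]
  used <- genome$used_bp[genome$used_bp$chrom == chrom, "pos"]
  for (i in 1:500) {
    p <- sample.int(hi - lo, 1L) + lo
    if ((!length(planted) || min(abs(planted - p)) >= 300) &&
        (!length(used) || min(abs(used - p)) >= 1000)) {
      return(p)
    }
  }
  stop("could not place a breakpoint on ", chrom)
}

mark_used <- function(genome, chrom, pos, rss_idx = NULL) {
  if (is.null(genome$used_bp)) {
    genome$used_bp <- data.frame(chrom = character(0), pos = integer(0))
  }
  genome$used_bp <- rbind(genome$used_bp,
                          data.frame(chrom = chrom, pos = as.integer(pos)))
  if (!is.null(rss_idx)) genome$planted_rss$used[rss_idx] <- TRUE
  genome
}

#' Simulate one ectopic structural variant
#'
#' Breakpoints are placed at planted cryptic heptamers according to
#' `rss_mode` ("both" ends, "one" end, or "none"), with RAG-like geometry:
#' a CAC-orientation heptamer immediately right of breakpoint 1 and a
#' GTG-orientation heptamer ending at breakpoint 2.  Junction chemistry is
#' drawn as insertion (mode-dependent probability), else microhomology of
#' length uniform on 1..`microhomology_max`, else blunt.
#'
#' @param genome A `toy_genome`.
#' @param sv_class One of DEL, DUP, INV, TRA (TRA requires two chromosomes).
#' @param rss_mode "both", "one" or "none".
#' @param config A [sim_config()].
#' @param germline Mark the truth as germline (shared with the control).
#' @param chem Optionally force a chemistry:
#'   `list(type = "microhomology", m = 3L, ins_len = 0L)` etc.
#' @return List with `truth` (an `sv_truth`) and the updated `genome`.
#' @export
simulate_ectopic_sv <- function(genome, sv_class = c("DEL", "DUP", "INV", "TRA"),
                                rss_mode = c("none", "one", "both"),
                                config, germline = FALSE, chem = NULL) {
  sv_class <- match.arg(sv_class)
  rss_mode <- match.arg(rss_mode)
  if (is.null(genome$used_bp)) {
    genome$used_bp <- data.frame(chrom = character(0), pos = integer(0))
  }
  if (sv_class == "TRA" && length(genome$chromosomes) < 2) {
    stop("TRA requires at least two chromosomes")
  }
  ins_fraction <- if (rss_mode == "none") config$insertion_fraction_plain
                  else config$insertion_fraction_rss_ectopic
  if (is.null(chem)) chem <- draw_chemistry(config, ins_fraction)

  chroms <- names(genome$chromosomes)
  pinned1 <- pinned2 <- FALSE
  i1 <- i2 <- NA_integer_

  df <- genome$planted_rss
  free <- function(ori) which(!df$used & !df$is_canonical &
                              df$orientation == ori)
  if (rss_mode == "both") {
    # choose a geometrically valid pair jointly: intra events need the
    # GTG-end site >= 5 kb downstream of the CAC site on one chromosome
    same <- sv_class != "TRA"
    c1s <- free("+")
    c2s <- free("-")
    pair <- NULL
    for (i in sample(c1s)) {
      ok <- if (same) {
        df$chrom[c2s] == df$chrom[i] & df$offset[c2s] + 7L > df$offset[i] + 5000
      } else {
        df$chrom[c2s] != df$chrom[i]
      }
      if (any(ok)) {
        pair <- c(i, if (sum(ok) == 1) c2s[ok] else sample(c2s[ok], 1L))
        break
      }
    }
    if (is.null(pair)) {
      stop("fewer than 2 unused cryptic plantings with the required geometry")
    }
    i1 <- pair[1]; i2 <- pair[2]
    chrom1 <- df$chrom[i1]; p1 <- df$offset[i1]
    chrom2 <- df$chrom[i2]; p2 <- df$offset[i2] + 7L
    pinned1 <- pinned2 <- TRUE
  } else if (rss_mode == "one") {
    cand <- free("+")
    if (sv_class != "TRA") {
      lens <- nchar(genome$chromosomes)
      cand <- cand[df$offset[cand] + 8000 < lens[df$chrom[cand]]]
    }
    if (!length(cand)) stop("no unused cryptic '+' planting available")
    i1 <- if (length(cand) == 1) cand else sample(cand, 1L)
    chrom1 <- df$chrom[i1]
    p1 <- df$offset[i1]
    pinned1 <- TRUE
    if (sv_class == "TRA") {
      chrom2 <- sample(setdiff(chroms, chrom1), 1)
      p2 <- random_breakpoint(genome, chrom2)
    } else {
      chrom2 <- chrom1
      p2 <- random_breakpoint(genome, chrom1, min_pos = p1 + 5000)
    }
  } else {
    chrom1 <- if (sv_class == "TRA") sample(chroms, 1) else
      sample(chroms, 1, prob = nchar(genome$chromosomes))
    p1 <- random_breakpoint(genome, chrom1,
                            max_pos = if (sv_class == "TRA") NULL else
                              nchar(genome$chromosomes[[chrom1]]) - 8000L)
    if (sv_class == "TRA") {
      chrom2 <- sample(setdiff(chroms, chrom1), 1)
      p2 <- random_breakpoint(genome, chrom2)
    } else {
      chrom2 <- chrom1
      p2 <- random_breakpoint(genome, chrom1, min_pos = p1 + 5000)
    }
  }

  if (sv_class == "TRA" && chrom1 == chrom2) {
    stop("TRA breakpoints must be on different chromosomes")
  }
  sv <- new_sv_call(chrom1, p1, chrom2, p2, sv_class,
                    orient1 = if (sv_class == "INV") "+" else "+",
                    orient2 = if (sv_class %in% c("INV", "DUP")) "-" else "+")
  pc <- plant_chemistry(genome, sv, chem, pinned1 = pinned1,
                        pinned2 = pinned2)
  genome <- pc$genome
  truth <- new_sv_truth(genome, sv, pc$ins,
                        rss_left = if (pinned1) genome$planted_rss$offset[i1]
                                   else NA_integer_,
                        rss_right = if (pinned2) genome$planted_rss$offset[i2]
                                    else NA_integer_,
                        germline = germline)
  genome <- mark_used(genome, chrom1, p1, rss_idx = i1)
  genome <- mark_used(genome, chrom2, p2,
                      rss_idx = if (!is.na(i2)) i2 else NULL)
  list(truth = truth, genome = genome)
}

#' Draw ectopic SV classes from the configured multinomial
#'
#' @param n Number of draws.
#' @param config A [sim_config()]; `class_weights` holds the multinomial
#'   weights (default the p53-null tumor composition 49:25:17:0).
#' @return Character vector of classes.
#' @export
draw_sv_classes <- function(n, config) {
  w <- config$class_weights
  sample(names(w), n, replace = TRUE, prob = w / sum(w))
}
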