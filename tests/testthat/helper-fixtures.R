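# Shared fixture builders.  Everything is generated in code at test time.

# random 41-bp window, optionally with a planted heptamer
make_window <- function(plant = FALSE, heptamer = "CACAGTG") {
  bg <- paste(sample(c("A", "C", "G", "T"), 41, replace = TRUE),
              collapse = "")
  if (!plant) return(bg)
  pos <- sample.int(41 - nchar(heptamer) + 1, 1)
  substr(bg, pos, pos + nchar(heptamer) - 1) <- heptamer
  bg
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# compact study configuration for harmonizer fixtures
small_study_config <- function(seed) {
  sim_config(seed = seed,
             chromosome_lengths = c(chr1 = 800000, chr2 = 400000),
             n_vdj_events = 4L, n_ectopic_rss = 8L, n_ectopic_plain = 12L,
             n_germline = 6L, n_canonical_rss = 30L, n_cryptic_rss = 60L)
}

# truth list with minimal fields for the caller-output simulator
fake_truths <- function(n, chrom = "chr1", spacing = 150L, span = 60L,
                        start = 1000L) {
  lapply(seq_len(n), function(i) {
    p1 <- start + (i - 1L) * spacing
    structure(list(sv = rearrangr:::new_sv_call(chrom, p1, chrom,
                                                p1 + span, "DEL"),
                   terminal = FALSE), class = "sv_truth")
  })
}

fake_genome <- function(len = 1e6, chrom = "chr1") {
  list(chromosomes = stats::setNames(strrep("A", len), chrom))
}

# build a chemistry fixture from scratch: four 20-bp contexts and a
# junction with a known attribution
make_chem_fixture <- function(kind = c("blunt", "microhomology",
                                       "insertion"),
                              m = 3L, ins = NULL) {
  kind <- match.arg(kind)
  pick_not <- function(not) sample(setdiff(c("A", "C", "G", "T"), not), 1)
  flankL <- rand_seq(20)
  contL <- rand_seq(20)
  preR <- rand_seq(20)
  flankR <- rand_seq(20)
  if (kind == "blunt") {
    substr(flankR, 1, 1) <- pick_not(substr(contL, 1, 1))
    substr(flankL, 20, 20) <- pick_not(substr(preR, 20, 20))
    mid <- ""
    truth <- list(chemistry = "blunt", mh = 0L, ins = "")
  } else if (kind == "microhomology") {
    substr(flankR, 1, m) <- substr(contL, 1, m)
    substr(flankR, m + 1, m + 1) <- pick_not(substr(contL, m + 1, m + 1))
    substr(flankL, 20, 20) <- pick_not(substr(preR, 20, 20))
    mid <- ""
    truth <- list(chemistry = "microhomology", mh = as.integer(m),
                  ins = "")
  } else {
    if (!is.null(ins)) {
      # fixed insert: keep the contexts from absorbing its end bases
      substr(contL, 1, 1) <- pick_not(substr(ins, 1, 1))
      substr(preR, 20, 20) <- pick_not(substr(ins, nchar(ins), nchar(ins)))
    }
    if (is.null(ins)) {
      len <- sample.int(8, 1)
      ins <- rand_seq(len)
      if (len == 1) {
        ins <- sample(setdiff(c("A", "C", "G", "T"),
                              c(substr(contL, 1, 1), substr(preR, 20, 20))),
                      1)
      } else {
        substr(ins, 1, 1) <- pick_not(substr(contL, 1, 1))
        substr(ins, len, len) <- pick_not(substr(preR, 20, 20))
      }
    }
    substr(flankR, 1, 1) <- pick_not(substr(contL, 1, 1))
    substr(flankL, 20, 20) <- pick_not(substr(preR, 20, 20))
    mid <- ins
    truth <- list(chemistry = "insertion", mh = 0L, ins = ins)
  }
  # pad the read beyond the 20-bp reference contexts, as a real consensus
  # read would extend past them
  junction <- paste0(rand_seq(10), flankL, mid, flankR, rand_seq(10))
  list(junction = junction, join = 30L,
       flankL = flankL, contL = contL, preR = preR,
       flankR = flankR, truth = truth)
}

# exhaustive alignment oracle for junction chemistry: score every
# (left-anchor, right-anchor) placement of the two flanks by total matched
# bases (with contiguous context extensions), take the best, and read off
# the attribution.  Independent of the anchored-search implementation.
chemistry_oracle <- function(junction, flankL, contL, preR, flankR) {
  n <- nchar(junction)
  jc <- strsplit(junction, "")[[1]]
  fL <- strsplit(flankL, "")[[1]]
  fR <- strsplit(flankR, "")[[1]]
  cL <- strsplit(contL, "")[[1]]
  pR <- strsplit(preR, "")[[1]]
  best <- NULL
  for (a in 20:n) {                     # flankL occupies a-19 .. a
    mL <- sum(jc[(a - 19):a] == fL)
    if (mL < 15) next
    for (b in 1:(n - 19)) {             # flankR occupies b .. b+19
      if (b <= a - 19) next
      mR <- sum(jc[b:(b + 19)] == fR)
      if (mR < 15) next
      # contiguous extensions
      ext_f <- 0L
      while (a + ext_f + 1 <= n && ext_f + 1 <= 20 &&
             jc[a + ext_f + 1] == cL[ext_f + 1]) ext_f <- ext_f + 1L
      ext_b <- 0L
      while (b - ext_b - 1 >= 1 && ext_b + 1 <= 20 &&
             jc[b - ext_b - 1] == pR[20 - ext_b]) ext_b <- ext_b + 1L
      score <- mL + mR + ext_f + ext_b
      overlap <- (a + ext_f) - (b - ext_b) + 1L
      cand <- list(score = score, a = a, b = b, ext_f = ext_f,
                   ext_b = ext_b, overlap = overlap)
      if (is.null(best) || score > best$score ||
          (score == best$score && overlap > best$overlap)) best <- cand
    }
  }
  if (is.null(best)) {
    return(list(chemistry = "unresolved", microhomology_len = 0L,
                inserted_bases = ""))
  }
  L_reach <- best$a + best$ext_f
  R_reach <- best$b - best$ext_b
  if (L_reach >= R_reach - 1L) {
    ov <- L_reach - R_reach + 1L
    list(chemistry = if (ov > 0) "microhomology" else "blunt",
         microhomology_len = max(ov, 0L), inserted_bases = "")
  } else {
    list(chemistry = "insertion", microhomology_len = 0L,
         inserted_bases = substr(junction, L_reach + 1L, R_reach - 1L))
  }
}

# reference windows + classification helper for truth records
classify_truth <- function(truth, genome, ...) {
  rec <- junction_record("x", truth$junction_sequence,
                         truth$context$flank_left, truth$context$cont_left,
                         truth$context$pre_right,
                         truth$context$flank_right, truth$join)
  classify_vdj_junction(rec, truth$sv, genome, ...)
}

truth_record <- function(truth, sv_id = "x") {
  junction_record(sv_id, truth$junction_sequence,
                  truth$context$flank_left, truth$context$cont_left,
                  truth$context$pre_right, truth$context$flank_right,
                  truth$join)
}
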