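# Junction windows, cRSS scanning, V(D)J joint typing and chemistry
# attribution.

test_that("junction windows are cut and orientation-adjusted correctly", {
  cfg <- sim_config(seed = 61)
  g <- generate_genome(cfg)
  r <- simulate_ectopic_sv(g, "DEL", "none", cfg,
                           chem = list(type = "blunt", m = 0L,
                                       ins_len = 0L))
  g <- r$genome; t <- r$truth
  sv <- t$sv; sv$precise <- TRUE
  rec <- extract_junction_windows(sv, g, t$junction_sequence, sv_id = "d1")
  chrom <- g$chromosomes[[sv$chrom1]]
  expect_identical(rec$left_flank_ref,
                   substr(chrom, sv$pos1 - 19, sv$pos1))
  expect_identical(rec$right_flank_ref,
                   substr(chrom, sv$pos2 + 1, sv$pos2 + 20))
  expect_equal(nchar(rec$window41), 41L)
  # blunt deletion: 20 bp reference left + breakpoint base + 20 bp right
  expect_identical(rec$window41,
                   paste0(substr(chrom, sv$pos1 - 19, sv$pos1),
                          substr(chrom, sv$pos2 + 1, sv$pos2 + 21)))
  # inversion: the right flank is the reverse complement of the reference
  # left of breakpoint 2
  ri <- simulate_ectopic_sv(g, "INV", "none", cfg,
                            chem = list(type = "blunt", m = 0L,
                                        ins_len = 0L))
  g <- ri$genome; ti <- ri$truth
  svi <- ti$sv; svi$precise <- TRUE
  reci <- extract_junction_windows(svi, g, ti$junction_sequence)
  expect_identical(reci$right_flank_ref,
                   revcomp(substr(g$chromosomes[[svi$chrom1]],
                                  svi$pos2 - 19, svi$pos2)))
  # short consensus and imprecise SVs are rejected
  expect_error(extract_junction_windows(sv, g, substr(t$junction_sequence,
                                                      1, 30)),
               "shorter than 41")
  # breakpoint too close to the chromosome end
  sv_edge <- sv; sv_edge$pos1 <- 10L; sv_edge$pos2 <- 6000L
  expect_error(extract_junction_windows(sv_edge, g, t$junction_sequence),
               "chromosome end")
  svq <- sv; svq$precise <- FALSE
  expect_warning(out <- extract_junction_windows(svq, g,
                                                 t$junction_sequence),
                 "imprecise")
  expect_null(out)
})

test_that("scan_crss finds canonical heptamers in both orientations", {
  h <- scan_crss("AAAACACAGTGAAAA")
  expect_equal(nrow(h), 1L)
  expect_identical(h$orientation, "CAC")
  expect_identical(h$matched7, "CACAGTG")
  expect_equal(h$score, 4L)
  expect_equal(h$offset, 4L)
  h2 <- scan_crss("AAAACACTGTGAAAA")
  expect_equal(nrow(h2), 1L)
  expect_identical(h2$orientation, "GTG")
  expect_equal(h2$score, 4L)
})

test_that("scan_crss agrees with an exhaustive 7-mer oracle on random sequence", {
  set.seed(62)
  tail_oracle <- function(k) sum(strsplit(k, "")[[1]][4:7] ==
                                   c("A", "G", "T", "G"))
  for (i in 1:40) {
    s <- rand_seq(41)
    hits <- scan_crss(s, min_score = 2)
    # oracle: enumerate every 7-mer window in both orientations; the best
    # orientation is reported, both on an exact tie
    expected <- 0L
    for (o in 0:(41 - 7)) {
      k <- substr(s, o + 1, o + 7)
      rc <- revcomp(k)
      sf <- if (startsWith(k, "CAC")) tail_oracle(k) else -1L
      sr <- if (startsWith(rc, "CAC")) tail_oracle(rc) else -1L
      if (max(sf, sr) >= 2) {
        expected <- expected + ifelse(sf == sr, 2L, 1L)
      }
    }
    expect_equal(nrow(hits), expected)
  }
})

test_that("scan_crss hit sets mirror under reverse complement", {
  set.seed(63)
  for (i in 1:25) {
    s <- rand_seq(60)
    fw <- scan_crss(s, min_score = 2)
    rv <- scan_crss(revcomp(s), min_score = 2)
    expect_equal(nrow(fw), nrow(rv))
    if (nrow(fw)) {
      mapped <- sort(nchar(s) - 7 - fw$offset)
      expect_equal(mapped, sort(rv$offset))
      key_f <- paste(sort(paste(nchar(s) - 7 - fw$offset,
                                ifelse(fw$orientation == "CAC", "GTG",
                                       "CAC"))), collapse = ";")
      key_r <- paste(sort(paste(rv$offset, rv$orientation)),
                     collapse = ";")
      expect_identical(key_f, key_r)
    }
  }
})

test_that("V(D)J joint typing recovers coding, signal, hybrid and none", {
  cfg <- sim_config(seed = 64, chromosome_lengths = c(chr1 = 1200000),
                    n_canonical_rss = 120L, n_cryptic_rss = 0L,
                    resection_mean = 0)
  g <- generate_genome(cfg)
  pairs <- rearrangr:::pair_canonical_sites(g, 40)
  got <- list(coding = character(0), signal = character(0),
              hybrid = character(0))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    emit <- if (i <= 25) c("coding", "signal") else "hybrid"
    res <- simulate_vdj_event(g, g$planted_rss[p, ], cfg, emit = emit)
    g <- res$genome
    g$planted_rss$used[p] <- TRUE
    for (t in res$truths) {
      cl <- classify_truth(t, g)
      got[[t$vdj_joint_type]] <- c(got[[t$vdj_joint_type]], cl$joint_type)
    }
  }
  # zero resection: perfect diagonal
  expect_true(all(got$coding == "coding"))
  expect_true(all(got$signal == "signal"))
  expect_true(all(got$hybrid == "hybrid"))
  # RSS-free junctions type as none
  res_none <- character(0)
  for (i in 1:25) {
    r <- simulate_ectopic_sv(g, "DEL", "none", cfg)
    g <- r$genome
    res_none <- c(res_none, classify_truth(r$truth, g)$joint_type)
  }
  expect_true(all(res_none == "none"))
})

test_that("resection degrades coding-joint recall gracefully, never to a wrong class", {
  cfg <- sim_config(seed = 65, chromosome_lengths = c(chr1 = 1500000),
                    n_canonical_rss = 220L, n_cryptic_rss = 0L,
                    resection_mean = 2)
  g <- generate_genome(cfg)
  pairs <- rearrangr:::pair_canonical_sites(g, 80)
  calls <- character(0)
  for (p in pairs) {
    res <- simulate_vdj_event(g, g$planted_rss[p, ], cfg, emit = "coding")
    g <- res$genome
    g$planted_rss$used[p] <- TRUE
    calls <- c(calls, classify_truth(res$truths[[1]], g)$joint_type)
  }
  expect_true(all(calls %in% c("coding", "none")))
  expect_gte(mean(calls == "coding"), 0.9)
})

test_that("chemistry attribution recovers planted fixtures", {
  fix <- make_chem_fixture("microhomology", m = 3L)
  rec <- junction_record("m3", fix$junction, fix$flankL, fix$contL,
                         fix$preR, fix$flankR, join = fix$join)
  out <- call_chemistry(rec)
  expect_identical(out$chemistry, "microhomology")
  expect_equal(out$microhomology_len, 3L)
  fix2 <- make_chem_fixture("insertion", ins = "GGATC")
  rec2 <- junction_record("i5", fix2$junction, fix2$flankL, fix2$contL,
                          fix2$preR, fix2$flankR, join = fix2$join)
  out2 <- call_chemistry(rec2)
  expect_identical(out2$chemistry, "insertion")
  expect_identical(out2$inserted_bases, "GGATC")
  expect_equal(out2$microhomology_len, 0L)
  fix3 <- make_chem_fixture("blunt")
  rec3 <- junction_record("b0", fix3$junction, fix3$flankL, fix3$contL,
                          fix3$preR, fix3$flankR, join = fix3$join)
  expect_identical(call_chemistry(rec3),
                   list(chemistry = "blunt", microhomology_len = 0L,
                        inserted_bases = ""))
})

test_that("chemistry calls agree with the exhaustive alignment oracle", {
  set.seed(66)
  kinds <- sample(c("blunt", "microhomology", "insertion"), 1000,
                  replace = TRUE)
  n_checked <- 0L
  for (kind in kinds) {
    m <- sample.int(6, 1)
    fix <- make_chem_fixture(kind, m = m)
    rec <- junction_record("x", fix$junction, fix$flankL, fix$contL,
                           fix$preR, fix$flankR, join = fix$join)
    got <- call_chemistry(rec)
    oracle <- chemistry_oracle(fix$junction, fix$flankL, fix$contL,
                               fix$preR, fix$flankR)
    expect_identical(got$chemistry, oracle$chemistry)
    expect_equal(got$microhomology_len, oracle$microhomology_len)
    expect_identical(got$inserted_bases, oracle$inserted_bases)
    # both match the planted truth
    expect_identical(got$chemistry, fix$truth$chemistry)
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 1000L)
})

test_that("a junction that anchors to neither flank is unresolved, not blunt", {
  rec <- junction_record("u", rand_seq(60), rand_seq(20), rand_seq(20),
                         rand_seq(20), rand_seq(20), join = 30L)
  expect_identical(call_chemistry(rec)$chemistry, "unresolved")
})

test_that("junction type tables report per-group fractions that sum to one", {
  df <- data.frame(
    joint_type = c(rep("coding", 6), rep("none", 4)),
    chemistry = c(rep("insertion", 7), "blunt", "microhomology", "blunt"))
  groups <- rep(c("vdj", "ectopic"), each = 5)
  tab <- junction_type_table(df, groups)
  expect_equal(tab$insertion + tab$microhomology + tab$blunt, c(1, 1),
               tolerance = 1e-9)
  expect_equal(tab$coding + tab$signal + tab$hybrid + tab$none, c(1, 1),
               tolerance = 1e-9)
  expect_no_warning(junction_type_table(df[0, ], character(0)))
  expect_warning(
    junction_type_table(data.frame(joint_type = "none",
                                   chemistry = "unresolved"), "g"),
    "omitted")
})
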