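# Generator invariants: plantings, determinism, junction construction,
# class composition, BFB segment bookkeeping, depth and caller noise.

test_that("planted heptamers are written at their recorded offsets", {
  cfg <- sim_config(seed = 1, chromosome_lengths = c(chr1 = 100000),
                    n_canonical_rss = 10L, n_cryptic_rss = 20L)
  g <- generate_genome(cfg)
  expect_equal(nrow(g$planted_rss), 30L)
  for (i in seq_len(nrow(g$planted_rss))) {
    p <- g$planted_rss[i, ]
    written <- substr(g$chromosomes[[p$chrom]], p$offset + 1, p$offset + 7)
    expect_identical(written,
                     if (p$orientation == "+") p$heptamer
                     else revcomp(p$heptamer))
    if (p$is_canonical) expect_identical(p$heptamer, "CACAGTG")
    else expect_match(p$heptamer, "^CAC[AC][CG][AT][GC]$")
  }
  # spacing guard: no second planting within 50 bp
  offs <- sort(g$planted_rss$offset)
  expect_true(all(diff(offs) >= 50))
})

test_that("genome generation is byte-identical under a fixed seed and differs across seeds", {
  cfg1 <- sim_config(seed = 1, chromosome_lengths = c(chr1 = 50000),
                     n_canonical_rss = 10L, n_cryptic_rss = 10L)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_genome_fasta(generate_genome(cfg1), f1)
  write_genome_fasta(generate_genome(cfg1), f2)
  expect_identical(readLines(f1), readLines(f2))
  g2 <- generate_genome(sim_config(seed = 2,
                                   chromosome_lengths = c(chr1 = 50000),
                                   n_canonical_rss = 10L,
                                   n_cryptic_rss = 10L))
  g1 <- generate_genome(cfg1)
  expect_false(identical(g1$chromosomes, g2$chromosomes))
  expect_equal(nrow(g1$planted_rss), nrow(g2$planted_rss))
  unlink(c(f1, f2))
})

test_that("chromosomes shorter than 1 kb are rejected", {
  expect_error(sim_config(chromosome_lengths = c(chr1 = 500)),
               "shorter than 1 kb")
})

test_that("V(D)J coding joints exclude heptamers; signal joints fuse them head-to-head", {
  cfg <- sim_config(seed = 11, chromosome_lengths = c(chr1 = 300000),
                    n_canonical_rss = 30L, n_cryptic_rss = 0L,
                    resection_mean = 0, insertion_fraction_vdj = 0)
  g <- generate_genome(cfg)
  pairs <- rearrangr:::pair_canonical_sites(g, 5)
  for (p in pairs) {
    res <- simulate_vdj_event(g, g$planted_rss[p, ], cfg)
    g <- res$genome
    g$planted_rss$used[p] <- TRUE
    coding <- res$truths[[1]]; signal <- res$truths[[2]]
    expect_identical(coding$vdj_joint_type, "coding")
    expect_identical(coding$chemistry, "blunt")
    # junction equals the two coding flanks concatenated
    jl <- substr(coding$junction_sequence, 1, 30)
    jr <- substr(coding$junction_sequence, 31, 60)
    p1 <- coding$sv$pos1; p2 <- coding$sv$pos2
    expect_identical(jl, substr(g$chromosomes[["chr1"]], p1 - 29, p1))
    expect_identical(jr, substr(g$chromosomes[["chr1"]], p2 + 1, p2 + 30))
    # no heptamer in either orientation within 7 bp of the join
    near <- substr(coding$junction_sequence, 24, 37)
    expect_false(grepl("CACAGTG", near, fixed = TRUE))
    expect_false(grepl("CACTGTG", near, fixed = TRUE))
    # signal joint: ...CACTGTG | CACAGTG...
    expect_identical(signal$vdj_joint_type, "signal")
    expect_identical(substr(signal$junction_sequence, 24, 30), "CACTGTG")
    expect_identical(substr(signal$junction_sequence, 31, 37), "CACAGTG")
  }
})

test_that("insertion_fraction_vdj = 1 gives inserted bases at every coding joint", {
  cfg <- sim_config(seed = 12, chromosome_lengths = c(chr1 = 300000),
                    n_canonical_rss = 30L, n_cryptic_rss = 0L,
                    insertion_fraction_vdj = 1)
  g <- generate_genome(cfg)
  pairs <- rearrangr:::pair_canonical_sites(g, 6)
  for (p in pairs) {
    res <- simulate_vdj_event(g, g$planted_rss[p, ], cfg, emit = "coding")
    g <- res$genome
    g$planted_rss$used[p] <- TRUE
    ins <- res$truths[[1]]$inserted_bases
    expect_gte(nchar(ins), 1)
    expect_lte(nchar(ins), 10)
    expect_identical(res$truths[[1]]$chemistry, "insertion")
  }
})

test_that("planted microhomology is attributable to both reference sides", {
  cfg <- sim_config(seed = 13)
  g <- generate_genome(cfg)
  r <- simulate_ectopic_sv(g, "DEL", "none", cfg,
                           chem = list(type = "microhomology", m = 3L,
                                       ins_len = 0L))
  t <- r$truth; g <- r$genome
  expect_identical(t$chemistry, "microhomology")
  expect_identical(t$microhomology_len, 3L)
  # the 3 bp left of the (maximally shifted) junction point equal the
  # reference 3 bp right of the second breakpoint, and the reference 3 bp
  # right of the first breakpoint
  mh <- substr(t$junction_sequence, 31, 33)
  chrom <- g$chromosomes[[t$sv$chrom1]]
  expect_identical(mh, substr(chrom, t$sv$pos2 + 1, t$sv$pos2 + 3))
  expect_identical(mh, substr(chrom, t$sv$pos1 + 1, t$sv$pos1 + 3))
})

test_that("RSS-pinned ectopic SVs carry anchored heptamers in both breakpoint windows", {
  cfg <- sim_config(seed = 14)
  g <- generate_genome(cfg)
  for (i in 1:6) {
    r <- simulate_ectopic_sv(g, "DEL", "both", cfg)
    g <- r$genome
    sv <- r$truth$sv
    w1 <- substr(g$chromosomes[[sv$chrom1]], sv$pos1 - 19, sv$pos1 + 21)
    w2 <- substr(g$chromosomes[[sv$chrom2]], sv$pos2 - 19, sv$pos2 + 21)
    h1 <- scan_crss(w1, min_score = 0)
    h2 <- scan_crss(w2, min_score = 0)
    expect_true(any(h1$orientation == "CAC" & h1$offset == 20))
    expect_true(any(h2$orientation == "GTG" & h2$offset + 7 == 20))
  }
})

test_that("RSS-pinned events fail cleanly when plantings run out", {
  cfg <- sim_config(seed = 16, n_cryptic_rss = 0L)
  g <- generate_genome(cfg)
  expect_error(simulate_ectopic_sv(g, "DEL", "both", cfg),
               "unused cryptic plantings")
  # V(D)J events require same-chromosome convergent canonical sites
  cfg2 <- sim_config(seed = 17)
  g2 <- generate_genome(cfg2)
  pr <- g2$planted_rss
  fw <- pr[pr$is_canonical & pr$orientation == "+" & pr$chrom == "chr1", ][1, ]
  rv <- pr[pr$is_canonical & pr$orientation == "-" & pr$chrom == "chr2", ][1, ]
  if (!is.na(fw$chrom) && !is.na(rv$chrom)) {
    expect_error(simulate_vdj_event(g2, rbind(fw, rv), cfg2),
                 "intra-chromosomal")
  }
})

test_that("ectopic class draws follow the configured multinomial", {
  cfg <- sim_config(seed = 15)
  set.seed(99)
  cls <- draw_sv_classes(10000, cfg)
  counts <- table(factor(cls, c("DEL", "DUP", "INV", "TRA")))
  w <- cfg$class_weights
  # chi-square GOF against the intended weights (oracle: stats::chisq.test)
  gof <- suppressWarnings(
    stats::chisq.test(counts[w > 0], p = w[w > 0] / sum(w)))
  expect_gt(gof$p.value, 0.01)
  set.seed(99)
  expect_identical(cls, draw_sv_classes(10000, cfg))
})

test_that("one BFB cycle doubles the fusion-proximal region and emits one fold-back", {
  cfg <- sim_config(seed = 20, chromosome_lengths = c(chr9 = 4e6),
                    n_canonical_rss = 0L, n_cryptic_rss = 0L)
  g <- generate_genome(cfg)
  res <- simulate_bfb(g, bfb_config("chr9", n_cycles = 1,
                                    bridge_break_sd = 4e5), cfg)
  inv <- Filter(function(t) !isTRUE(t$terminal), res$truths)
  expect_length(inv, 1L)
  expect_identical(inv[[1]]$sv$sv_class, "INV")
  # independent enumeration from the signed segment string
  mult <- segment_multiplicity(res$segment_string, 4e6, cfg$window_size)
  expect_identical(max(mult$multiplicity), 2L)
})

test_that("k BFB cycles never exceed multiplicity 2^k and conserve sequence content", {
  for (k in c(2L, 4L)) {
    cfg <- sim_config(seed = 20 + k, chromosome_lengths = c(chr9 = 5e6),
                      n_canonical_rss = 0L, n_cryptic_rss = 0L)
    g <- generate_genome(cfg)
    res <- simulate_bfb(g, bfb_config("chr9", n_cycles = k), cfg)
    mult <- segment_multiplicity(res$segment_string, 5e6, cfg$window_size)
    expect_lte(max(mult$multiplicity), 2^k)
    # conservation: windowed bp coverage sums to the structure length
    expect_equal(sum(mult$bp), rearrangr:::seg_len(res$segments))
    # profile agrees with the simulator's own bookkeeping
    expect_identical(mult$multiplicity, res$cn_profile$multiplicity)
    # fold-back spans bounded by twice the sister-break jitter
    fb <- Filter(function(t) !isTRUE(t$terminal), res$truths)
    spans <- vapply(fb, function(t) t$sv$pos2 - t$sv$pos1, numeric(1))
    expect_true(all(spans <= 2 * 500))
  }
})

test_that("BFB amplicons reach the 3-12 copy range", {
  hit <- FALSE
  for (s in 1:20) {
    cfg <- sim_config(seed = 100 + s, chromosome_lengths = c(chr9 = 4e6),
                      n_canonical_rss = 0L, n_cryptic_rss = 0L)
    g <- generate_genome(cfg)
    res <- simulate_bfb(g, bfb_config("chr9", n_cycles = 4,
                                      bridge_break_sd = 3e5), cfg)
    cn <- res$cn_profile$copy_number
    if (any(cn >= 3 & cn <= 12)) { hit <- TRUE; break }
  }
  expect_true(hit)
})

test_that("read depth follows the Poisson model and is reproducible", {
  prof <- data.frame(chrom = "chr1",
                     window_start = seq(0, by = 50000, length.out = 300),
                     copy_number = 2L)
  d1 <- simulate_read_depth(prof, 1000, seed = 7)
  d2 <- simulate_read_depth(prof, 1000, seed = 7)
  expect_identical(d1, d2)
  # null case: mean ratio within 3 standard errors of 1
  ratio <- d1$tumor_count / d1$control_count
  se <- stats::sd(ratio) / sqrt(nrow(d1))
  expect_lt(abs(mean(ratio) - 1), 3 * se)
  # CN 6 at coverage 1000: expected tumor count 3000
  prof6 <- transform(prof, copy_number = 6L)
  d6 <- simulate_read_depth(prof6, 1000, seed = 8)
  se6 <- stats::sd(d6$tumor_count) / sqrt(nrow(d6))
  expect_lt(abs(mean(d6$tumor_count) - 3000), 3 * se6)
  expect_error(simulate_read_depth(prof, 0), "coverage_mean")
})

test_that("noiseless callers reproduce the truth breakpoints exactly", {
  g <- fake_genome(1e6)
  truths <- fake_truths(50)
  out <- simulate_caller_outputs(truths, g, n_callers = 3,
                                 sensitivity = 1, jitter_sd = 0,
                                 fp_per_caller = 0, seed = 3)
  base <- rearrangr:::truths_to_calls(truths)
  for (calls in out$tumor) {
    expect_equal(nrow(calls), 50L)
    expect_identical(calls[, c("chrom1", "pos1", "chrom2", "pos2")],
                     base[, c("chrom1", "pos1", "chrom2", "pos2")])
  }
  out0 <- simulate_caller_outputs(truths, g, n_callers = 2,
                                  sensitivity = 0, jitter_sd = 0,
                                  fp_per_caller = 2, seed = 4)
  for (calls in out0$tumor) {
    expect_equal(nrow(calls), 2L)  # false positives only
  }
})

test_that("multi-caller detection matches the closed-form binomial rate", {
  # 3 callers at sensitivity 0.9: P(detected by >= 2) = 0.9^3 + 3*0.9^2*0.1
  g <- fake_genome(2e6)
  truths <- fake_truths(500, spacing = 3000L, start = 5000L)
  out <- simulate_caller_outputs(truths, g, n_callers = 3,
                                 sensitivity = 0.9, jitter_sd = 0,
                                 fp_per_caller = 0, seed = 5)
  pos1 <- vapply(truths, function(t) t$sv$pos1, numeric(1))
  ndet <- rowSums(vapply(out$tumor, function(calls) {
    pos1 %in% calls$pos1
  }, logical(500)))
  phat <- mean(ndet >= 2)
  p <- 0.9^3 + 3 * 0.9^2 * 0.1        # 0.972
  # binomial 99% bounds at n = 500
  bound <- 2.576 * sqrt(p * (1 - p) / 500)
  expect_lt(abs(phat - p), bound)
})

test_that("the full study is deterministic and round-trips through its files", {
  cfg <- small_study_config(31)
  st1 <- simulate_rearrangement_study(cfg)
  st2 <- simulate_rearrangement_study(cfg)
  expect_identical(truth_table(st1$truths), truth_table(st2$truths))
  expect_identical(st1$depth, st2$depth)
  expect_identical(st1$caller_output, st2$caller_output)
  dir <- tempfile()
  write_simulation(st1, dir)
  # BEDPE round-trip: write -> load preserves every call
  for (caller in names(st1$caller_output$tumor)) {
    orig <- st1$caller_output$tumor[[caller]]
    back <- load_bedpe(file.path(dir, paste0("tumor_", caller, ".bedpe")))
    expect_equal(back[, c("chrom1", "pos1", "chrom2", "pos2", "sv_class",
                          "support", "precise")],
                 orig[, c("chrom1", "pos1", "chrom2", "pos2", "sv_class",
                          "support", "precise")],
                 ignore_attr = TRUE)
  }
  # genome FASTA round-trip
  g2 <- read_genome_fasta(file.path(dir, "genome.fa"))
  expect_identical(g2$chromosomes, st1$genome$chromosomes)
  unlink(dir, recursive = TRUE)
})

test_that("every emitted junction is reconstructible from genome and truth", {
  cfg <- small_study_config(32)
  st <- simulate_rearrangement_study(cfg)
  for (t in st$truths) {
    if (isTRUE(t$terminal)) next
    rebuilt <- rearrangr:::build_junction_seq(st$genome, t$sv,
                                              mid = t$inserted_bases)
    expect_identical(rebuilt, t$junction_sequence)
  }
})
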