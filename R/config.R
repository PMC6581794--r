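#' Simulation configuration
#'
#' Bundles every knob of the synthetic rearrangement study into one validated
#' list.  Defaults reproduce the study conditions the analysis modules are
#' exercised against: insertion fractions of 0.73 for canonical V(D)J coding
#' joints and 0.60 for RSS-bearing ectopic SVs, geometric end resection with
#' mean 2 bp, and the p53-null ectopic class composition DEL:DUP:INV:TRA =
#' 49:25:17:0 as multinomial weights.
#'
#' @param seed Integer seed; every simulation routine is a pure function of
#'   (config, seed) and fixed seed implies byte-identical outputs.
#' @param chromosome_lengths Named numeric vector of chromosome sizes in bp.
#' @param n_vdj_events Number of canonical V(D)J deletion events.
#' @param n_ectopic_rss Ectopic SVs with a cryptic RSS at both breakpoints.
#' @param n_ectopic_plain Ectopic SVs without cryptic RSSs.
#' @param n_germline Germline SVs shared with the matched control.
#' @param insertion_fraction_vdj Probability a V(D)J coding joint carries a
#'   non-templated insertion (default 0.73).
#' @param insertion_fraction_rss_ectopic Same for RSS-bearing ectopic SVs
#'   (default 0.60).
#' @param insertion_fraction_plain Same for RSS-free ectopic SVs; these show
#'   no insertion bias, default 0.25.
#' @param mh_fraction_no_insertion Given no insertion, probability the
#'   junction shows microhomology (length uniform on 1..microhomology_max)
#'   rather than a blunt join.
#' @param resection_mean Mean of the geometric resection applied
#'   independently to each coding end, in bp.
#' @param microhomology_max Maximum planted microhomology length, bp.
#' @param coverage_mean Expected read count per 50-kb window at copy
#'   number 2.
#' @param class_weights Named multinomial weights for ectopic SV classes.
#' @param n_canonical_rss,n_cryptic_rss Number of canonical (CACAGTG) and
#'   degenerate cryptic heptamers planted per genome.
#' @param window_size Read-depth window size in bp (50 kb).
#' @param bfb Optional [bfb_config()] describing a breakage-fusion-bridge
#'   amplification on one chromosome.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chromosome_lengths = c(chr1 = 800000, chr2 = 400000),
                       n_vdj_events = 12L,
                       n_ectopic_rss = 28L,
                       n_ectopic_plain = 46L,
                       n_germline = 10L,
                       insertion_fraction_vdj = 0.73,
                       insertion_fraction_rss_ectopic = 0.60,
                       insertion_fraction_plain = 0.25,
                       mh_fraction_no_insertion = 0.7,
                       resection_mean = 2,
                       microhomology_max = 6L,
                       coverage_mean = 1000,
                       class_weights = c(DEL = 49, DUP = 25, INV = 17, TRA = 0),
                       n_canonical_rss = 80L,
                       n_cryptic_rss = 140L,
                       window_size = 50000L,
                       bfb = NULL) {
  cfg <- list(seed = as.integer(seed),
              chromosome_lengths = chromosome_lengths,
              n_vdj_events = as.integer(n_vdj_events),
              n_ectopic_rss = as.integer(n_ectopic_rss),
              n_ectopic_plain = as.integer(n_ectopic_plain),
              n_germline = as.integer(n_germline),
              insertion_fraction_vdj = insertion_fraction_vdj,
              insertion_fraction_rss_ectopic = insertion_fraction_rss_ectopic,
              insertion_fraction_plain = insertion_fraction_plain,
              mh_fraction_no_insertion = mh_fraction_no_insertion,
              resection_mean = resection_mean,
              microhomology_max = as.integer(microhomology_max),
              coverage_mean = coverage_mean,
              class_weights = class_weights,
              n_canonical_rss = as.integer(n_canonical_rss),
              n_cryptic_rss = as.integer(n_cryptic_rss),
              window_size = as.integer(window_size),
              bfb = bfb)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$insertion_fraction_vdj, cfg$insertion_fraction_rss_ectopic,
             cfg$insertion_fraction_plain, cfg$mh_fraction_no_insertion)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  counts <- c(cfg$n_vdj_events, cfg$n_ectopic_rss, cfg$n_ectopic_plain,
              cfg$n_germline, cfg$n_canonical_rss, cfg$n_cryptic_rss)
  if (any(counts < 0)) stop("all counts must be >= 0", call. = FALSE)
  if (is.null(names(cfg$chromosome_lengths)) ||
      any(!nzchar(names(cfg$chromosome_lengths)))) {
    stop("chromosome_lengths must be a named vector", call. = FALSE)
  }
  if (any(cfg$chromosome_lengths < 1000)) {
    stop("invalid config: chromosome shorter than 1 kb", call. = FALSE)
  }
  if (cfg$resection_mean < 0 || cfg$microhomology_max < 1 ||
      cfg$coverage_mean <= 0) {
    stop("resection_mean >= 0, microhomology_max >= 1 and coverage_mean > 0 required",
         call. = FALSE)
  }
  if (!is.null(cfg$bfb) && !inherits(cfg$bfb, "bfb_config")) {
    stop("bfb must be a bfb_config or NULL", call. = FALSE)
  }
  invisible(cfg)
}

#' Breakage-fusion-bridge cycle configuration
#'
#' @param chromosome Chromosome name carrying the amplicon.
#' @param initial_break 0-based offset of the seeding break; sequence distal
#'   to it is lost from the rearranged chromatid.
#' @param n_cycles Number of fusion-bridge-breakage cycles (1..8; copy
#'   number grows at most geometrically, so a desk-scale guard applies).
#' @param break_position_jitter Standard deviation (bp) of the offset
#'   between the two sister-chromatid break positions at each fusion; this
#'   bounds the span of the emitted fold-back inversions (<= 2x jitter).
#' @param bridge_break_sd Standard deviation (bp) of the per-cycle bridge
#'   rupture position relative to the previous fusion point; sets the width
#'   of the amplified staircase.
#' @param foldback_mh_prob,foldback_ins_prob Junction chemistry mix of the
#'   fold-back fusions (remainder is blunt).  BFB fusions are end-joining
#'   products, so short microhomology dominates by default.
#' @return An object of class `bfb_config`.
#' @export
bfb_config <- function(chromosome = "chr1",
                       initial_break = NULL,
                       n_cycles = 4L,
                       break_position_jitter = 500,
                       bridge_break_sd = 600000,
                       foldback_mh_prob = 0.7,
                       foldback_ins_prob = 0.15) {
  n_cycles <- as.integer(n_cycles)
  if (n_cycles < 1 || n_cycles > 8) {
    stop("n_cycles must be in 1..8", call. = FALSE)
  }
  if (break_position_jitter < 100) {
    stop("break_position_jitter must be >= 100 bp", call. = FALSE)
  }
  if (foldback_mh_prob + foldback_ins_prob > 1) {
    stop("foldback chemistry probabilities exceed 1", call. = FALSE)
  }
  structure(list(chromosome = chromosome,
                 initial_break = initial_break,
                 n_cycles = n_cycles,
                 break_position_jitter = break_position_jitter,
                 bridge_break_sd = bridge_break_sd,
                 foldback_mh_prob = foldback_mh_prob,
                 foldback_ins_prob = foldback_ins_prob),
            class = "bfb_config")
}
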