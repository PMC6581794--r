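---
title: "Simulating and dissecting complex genome rearrangements with rearrangr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and dissecting complex genome rearrangements with rearrangr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rearrangr)
```

## The scientific problem

Developing lymphocytes cut their own genome: the RAG1/2 nuclease initiates
V(D)J recombination by cleaving between coding gene segments and their
recombination signal sequences (RSSs), whose most conserved element is the
heptamer CACAGTG.  In p53-deficient T cells two distinct routes to genomic
instability coexist.  Off-target RAG cleavage at *cryptic* RSSs scattered
through the genome produces ectopic deletions and other structural variants
(SVs) whose breakpoint junctions look like aberrant V(D)J joints: heptamer
motifs in RAG-consistent orientation, resected ends, and non-templated (TdT)
insertions.  Independently of RAG, breakage-fusion-bridge (BFB) mitotic
cycles — breakage, sister-chromatid fusion into a dicentric, anaphase bridge
rupture — drive focal amplification with a recognizable fingerprint:
fold-back inversions, a copy-number staircase, tight CNV–SV colocalization,
and junctions sealed by short microhomology.

`rearrangr` implements the full analysis chain used to separate these two
signatures — multi-caller SV consensus and filtering, breakpoint-junction
sequence analysis, and CNV/amplicon characterization — together with a
synthetic-data generator that plants every feature with machine-readable
ground truth, so each stage is testable without any sequencing data.

## The synthetic-data generator

`generate_genome()` draws i.i.d. uniform ACGT background and plants
canonical (CACAGTG) and degenerate cryptic heptamers drawn from the
consensus CAC(A/C)(C/G)(A/T)(G/C), each at a recorded offset and
orientation, with at least 50 bp between plantings.  Uniform background
(GC = 0.5) is a deliberate choice over mouse-like composition: the chance
occurrence rate of CAC-anchored 7-mers is then analytically tractable, so
scanner false-positive rates can be checked in closed form.

Rearrangement events are planted with exact junction chemistry:

* **Canonical V(D)J events** (`simulate_vdj_event()`) use a convergent pair
  of canonical heptamers.  The coding joint excludes both heptamers,
  resects each coding end by an independent geometric draw (default mean
  2 bp — the distribution is not constrained by junction data, and the
  geometric is the maximum-entropy choice for a per-base nibbling process)
  and carries a 1–10 bp uniform-random non-templated insertion with
  probability 0.73, the observed insertion fraction at canonical joints.
  The reciprocal signal joint fuses the heptamer ends head-to-head
  (`...CACTGTG | CACAGTG...`), blunt and unresected.  Hybrid joints (one
  heptamer retained) can be emitted for classifier fixtures.
* **Ectopic SVs** (`simulate_ectopic_sv()`) place breakpoints at cryptic
  plantings (`rss_mode` = both/one ends) or at random positions, with
  RAG-consistent geometry: a CAC-orientation heptamer immediately right of
  breakpoint 1 and a GTG-orientation heptamer ending at breakpoint 2.
  Junction chemistry is drawn as insertion (probability 0.60 at RSS-bearing
  junctions, 0.25 at RSS-free ones, which show no insertion bias), else
  microhomology of length uniform on 1..6, else blunt.  Class frequencies
  default to the multinomial DEL:DUP:INV:TRA = 49:25:17:0.
* **BFB cycles** (`simulate_bfb()`) track the rearranged chromatid as a
  signed segment list.  Each cycle fuses the broken end with its sister
  chromatid (broken a small offset `d` earlier; `d` is bounded by twice
  `break_position_jitter`, so every fold-back inversion spans at most
  2×jitter), then ruptures the bridge at a position drawn half-Gaussian
  (`bridge_break_sd`) below the fusion; the daughter keeping both copies of
  the fusion-proximal region is followed, because the amplified clone is
  the one that expands and gets sequenced.  Two parameters are needed where
  a single "jitter" would conflate different length scales: the sister
  break offset (sub-kb; sets fold-back span) and the bridge rupture wander
  (hundreds of kb; sets the width of each staircase step).  The terminal
  loss distal to the seeding break is emitted as a junction-less deletion
  truth; bridge-break losses belong to the discarded daughter cell and are
  not emitted.  The copy-number profile reports chromatid multiplicity plus
  one intact homolog, so the background is diploid.
* **Caller noise** (`simulate_caller_outputs()`) detects each truth
  independently per caller, jitters breakpoints (Gaussian, truncated to the
  chromosome), assigns 3 + Poisson(5) read pairs of support, adds uniform
  false positives, and designates one caller "precise" with zero jitter.
  Germline truths appear in all tumor call sets and, jitter-free, in the
  matched control.

**Recorded truth is the maximal-parsimony attribution.**  After composing a
junction the generator forces a mismatch one base beyond every planted
boundary (always at a background position, never inside a planted heptamer
or homology tract) and records as truth the chemistry obtained by maximal
extension of both reference sides — the same convention any caller must
use, because a junction base that happens to match both references is
genuinely ambiguous.  One geometry admits no enforcement: an inversion with
cryptic RSSs at both ends fuses two CAC anchors, so its non-insertion
junctions inherently carry ≥3 bp of chance homology; the truth records the
measured value.

Determinism: every simulation routine is a pure function of the
configuration seed; equal configs give byte-identical FASTA/BEDPE/TSV
output.

## Multi-caller SV consensus and filtering

The harmonization chain is consensus → germline subtraction → support
filtering, each stage only shrinking the call set:

* **Matching** (`match_calls()`): chromosome pairs equal (unordered for
  translocations), both breakpoints within the window, classes equal when
  both calls are intra-chromosomal.  Each call carries an effective window
  — 150 bp by default, shrunk to 10 bp for calls flagged precise — and two
  calls are compared at the *larger* of their effective windows.  The
  larger-window rule matters: a split-read caller that localizes a
  breakpoint exactly must still be allowed to corroborate a read-pair
  caller whose estimate is tens of bp off; taking the smaller window would
  isolate precise callers from everyone else.  150 bp reflects the
  insert-size scale at which read-pair callers localize; orientation is not
  compared because caller strand conventions differ.
* **Consensus** (`consensus()`): single-linkage clustering of matching
  calls (union-find), retaining intra-chromosomal clusters supported by ≥2
  distinct callers and inter-chromosomal clusters by ≥3.  The
  representative takes the lexicographically first precise member's
  coordinates if any, else the support-weighted median per breakpoint; all
  tie-breaks are deterministic and the output is invariant to caller input
  order.
* **Germline subtraction** (`subtract_germline()`): a tumor SV matching any
  control call with ≥1 supporting read pair is removed; the class
  requirement is waived here, since the same germline event may be typed
  differently across call sets.
* **Support filter** (`filter_support()`): consensus best support ≥3 read
  pairs.  The threshold is applied to the consensus best support rather
  than per caller — the per-caller alternative would make retention depend
  on which caller happened to report fewer pairs.

## Breakpoint-junction analysis

`extract_junction_windows()` cuts the 41-bp window centered on the join (20
reference bp per side) and carries four orientation-adjusted 20-bp
reference contexts: the flank ending at the join and the reference
continuation past it, for each side (inversion sides are
reverse-complemented).  Both the reference-side windows and the
consensus-read window are retained, since motif discovery operates on the
read while orientation logic operates on the reference.

**Chemistry** (`call_chemistry()`): the junction is anchored to both flanks
(exact 20-mer match preferred, else best sliding alignment at ≥15/20
identity; below that the junction is *unresolved*, distinct from blunt),
then each anchor is extended along its reference continuation.  Overlap of
the two reaches is microhomology; a gap is a non-templated insertion; ties
prefer microhomology (maximal-overlap convention), and insertion is called
only when bases remain unmatched under every attribution.  The
implementation is verified against an exhaustive split-and-overlap
enumeration oracle on 1,000 random fixtures.

**Cryptic RSS scanning** (`scan_crss()`): a hit is a 7-mer with an exact
CAC anchor (or ending GTG in the reverse orientation) scoring ≥2 of 4
matches to the AGTG tail — consistent with the degenerate consensus
CAC(A/C)(C/G)(A/T)(G/C), in which every position beyond the anchor admits
two bases.  A 7-mer qualifying in both orientations is reported once with
the higher-scoring orientation.

**Joint typing** (`classify_vdj_junction()`): RAG consistency requires a
CAC-orientation heptamer anchored at, or within 10 bp right of, breakpoint
1 and a GTG-orientation heptamer ending at, or within 10 bp left of,
breakpoint 2, both in the reference.  The 10-bp tolerance absorbs
resection, which shifts apparent breakpoints outward: with geometric
resection of mean 2 per end, the probability that both heptamers stay
within tolerance is about 0.98, so coding-joint recall stays above 95%
while anchors destroyed by deep resection degrade to "none", never to a
wrong positive class.  (A tighter 3-bp tolerance would cap recall near
64%.)  Heptamer inclusion in the junction is then tested with a 14-bp probe
— the heptamer plus 7 bp of distal reference context, searched in both
orientations near the join.  The context disambiguates the two heptamer
copies, which are otherwise identical strings: both excluded → coding
joint; both included → signal joint; exactly one → hybrid joint.  The
default heptamer score threshold for joint typing is 4 (the perfect
CACAGTG), as canonical V(D)J typing is built on the perfect heptamer; lower
it to 2 to type junctions at degenerate cryptic RSSs.

**Motif discovery** (`discover_motif()`): ZOOPS (zero-or-one occurrence per
sequence) EM over both strands of the 41-bp windows, against a 0-order
background estimated from the windows.  Candidate seeds are the distinct
7-mers present, ranked by zero-or-one-per-sequence coverage; the top 3 are
refined by EM to convergence (relative log-likelihood change < 1e-6, at
most 200 iterations; the trace is monotone, as EM guarantees).  Running EM
from every distinct seed is supported (`n_candidates`), but coverage
ranking makes deeper refinement redundant: a genuinely shared motif always
ranks at the top, which is why 3 is the default.

Significance is calibrated empirically rather than by an analytic E-value:
the identical search runs on `n_shuffles` dinucleotide-preserving
(Altschul–Erickson) shuffles of the window set, and `empirical_e` is the
Bonferroni-style expected number of equally good motifs in shuffled data —
the number of distinct candidate seeds times the extreme-value (Gumbel,
moment-fitted) tail probability that a shuffled best log-likelihood ratio
reaches the observed one.  The EVD tail is what makes the statistic useful
on both sides: a planted motif sits far beyond any shuffled maximum and
gets an E-value many orders of magnitude below 1, while on pure background
the observed maximum is exchangeable with the shuffled maxima and the
candidate-count multiplier keeps E at or above 1.  A rank-based count alone
cannot resolve values below 1/(n_shuffles + 1) and would fail the planted
case at any affordable shuffle count.  The raw exceedance fraction is also
reported (`p_empirical`).

## Copy number, amplicons and the BFB score

Windowed tumor read counts are normalized as
(tumor/median tumor)/(control/median control) per 50-kb window
(`normalize_ratio()`); zero-control windows are masked.  Median anchoring
assumes the majority of windows are diploid.  Segmentation
(`segment_cn()`) is deliberately simple and deterministic: per-window copy
number = round(2 × ratio) clipped to [0, 64], equal-CN runs merged, runs
shorter than 3 windows absorbed into the neighbor with the closer mean
ratio, and segment CN re-estimated from the pooled mean.  At coverage ≥500
per window this recovers true integer CN for ≥95% of windows across CN
1–12; the residual errors sit on windows straddling true CN boundaries,
where any windowed estimate is ambiguous.

Amplicons are maximal unions of segments with CN ≥ 3, merged across gaps ≤
500 kb (`detect_amplicons()`).  For each amplicon,
`characterize_amplicons()` collects colocalized SVs (intra-chromosomal SVs
need both breakpoints inside; translocations with one breakpoint inside
are flagged separately), counts fold-back inversions (INV with breakpoint
distance ≤ 5 kb), and computes the microhomology fraction of resolved
junctions.  The BFB evidence score is the mean of three saturating
components — inversion fraction / 0.5, fold-back count / 2, microhomology
fraction / 0.5, each capped at 1 — so that amplicons matching the reported
hallmarks (≈60% inversions, multiple fold-backs, majority short-homology
junctions) saturate all three.  Tandem-duplication-driven amplicons, the
natural alternative explanation of focal gain, score at most 1/3 higher
than their microhomology component alone, giving a ≥0.3 separation from
BFB amplicons in simulation.

## Exact association tests

`fisher_exact_two_sided()` enumerates all 2×2 tables with the observed
margins in exact log-factorial arithmetic; the two-sided p sums the
probabilities of tables no more probable than the observed one (the
conventional small-p method), with a 1e-12 relative tolerance for
floating-point ties.  A zero margin returns p = 1, flagged degenerate.
This reproduces p = 0.007 for the 7/7-vs-2/8 early/late amplification
table and p ≈ 6.5e-4 (< 0.001, two-sided) for the 5/10-vs-12/177 cohort
table, and agrees with an independent enumeration oracle to 1e-12 on all
small-margin tables.  `cohort_summary()` rounds percentages half away from
zero to one decimal (10/12 → 83.3%).

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
study <- simulate_rearrangement_study(cfg)
consensus_svs <- harmonize_sv(study$caller_output$tumor,
                              study$caller_output$control, window = 150)
summarize_by_class(consensus_svs)
segments <- segment_cn(normalize_ratio(study$depth))
fisher_exact_two_sided(matrix(c(7, 0, 2, 6), 2, byrow = TRUE))
```

## Problem sizes used in the shipped checks

The test suite and the acceptance script run everything at desk scale,
chosen to keep each property statistically decisive while staying fast:
toy genomes of 0.4–12 Mb; 200 events per fixture class for the classifier
and insertion-fraction checks (binomial 95% bands at n = 200); motif
calibration on 100-window sets with 20–100 shuffles and 8–20 background
seeds; harmonizer recovery pooled over 10 seeded studies; BFB scoring over
10–20 seeded simulations at coverage 1000 with 3–5 cycles on a 12-Mb
chromosome.

## What the simulations do and do not show

The generator plants exactly the features the analysis modules are built
to detect, on uniform background with Poisson depth noise (a negative
binomial option exists for overdispersion, but Poisson is the null).  It
does not emulate mouse sequence composition, repeat structure, mappability
artifacts, tumor purity or subclonality, read-level errors, or the
internal behavior of any real SV caller — the caller model is a
sensitivity/jitter/false-positive abstraction of their output files, not
of their algorithms.  Passing these checks therefore demonstrates that the
statistical machinery is correct and calibrated on data with known truth,
not that any particular real data set will be called perfectly.  The real
cohort's genome-wide counts (total SV numbers, per-tumor amplification
status) depend on raw sequencing data and are outside what desk-scale
simulation can or should reproduce; only their printed contingency tables
and percentage arithmetic are recomputed.

## Known limitations

* The BFB model follows a single amplified daughter lineage; it does not
  model ongoing instability after telomere capture, chromothripsis, or
  inter-chromosomal BFB.
* RSS scoring is heptamer-only; full 12/23 spacer + nonamer models (RIC
  scores) are out of scope.
* Motif discovery reports the single best ungapped width-7 model (ZOOPS);
  multiple-motif reporting and gapped models are not implemented.
* Segmentation has no purity/ploidy correction; the diploid baseline is
  fixed at 2.
* The matched-control subtraction represents a single control; a panel of
  additional controls can be supplied as extra control call sets, but no
  panel-specific logic exists.
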