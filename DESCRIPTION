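Package: rearrangr
Title: Simulation and Analysis of Complex Genome Rearrangements in
    Lymphoid Tumors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying structural variation (SV) in tumor
    genomes where both RAG-nuclease off-target activity and
    breakage-fusion-bridge (BFB) mitotic cycles shape the
    rearrangement landscape.  Provides a synthetic-data generator
    (toy genomes with planted canonical and cryptic recombination
    signal sequence heptamers, SVs with defined breakpoint-junction
    chemistry, BFB amplicons with fold-back inversions and
    copy-number staircases, and noisy multi-caller call sets with a
    matched control); a multi-caller SV consensus and filtering
    chain (cross-caller matching, germline subtraction, read-pair
    support filtering); breakpoint-junction sequence analysis
    (cryptic RSS heptamer scanning, ZOOPS expectation-maximization
    motif discovery with an empirical significance calibration,
    coding/signal/hybrid V(D)J joint typing, and
    microhomology/non-templated-insertion chemistry calling);
    read-depth copy-number segmentation with amplicon detection and
    a BFB evidence score; and exact two-sided Fisher tests for
    cohort association tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
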