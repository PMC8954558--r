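Package: srrnascout
Title: Discovery and Permutation-Based Validation of rDNA-Derived Small RNA Targets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying small rDNA-derived RNAs (srRNAs): synthetic
    data generation for a scaled rDNA unit and a genome carrying diverged
    planted rDNA fragments, quality trimming and exact deduplication of
    small-RNA reads, a gapless mismatch-tolerant short-read aligner, the
    two-pass (reads to rDNA to genome) srRNA selection pipeline with
    target-gene assignment, epigenomic context analysis (z-scored signal
    metaprofiles, chromatin-state composition, bidirectional TSS
    classification), and the statistical validation machinery: within-read
    shuffling permutation nulls, interval Jaccard statistics, hypergeometric
    overlap tests, and Monte-Carlo calibration of the Mann-Whitney U-test on
    zero-inflated expression data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
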