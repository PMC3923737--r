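Package: seedmir
Title: Small RNA Analysis of Developing Oilseed Seeds: miRNA Discovery,
    IsomiR Profiling, Differential Representation and Target Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a seed small-RNA analysis
    pipeline: read cleaning (quality, N-content, adapter trimming, length
    window), removal of non-coding and organellar RNA classes, conserved
    miRNA identification by perfect matching against a mature miRNA
    reference, pre-miRNA discovery by block-anchored read patterns combined
    with hairpin minimum-free-energy (MFE) and MFE-index (MFEI) screening,
    isomiR profiling, stage-wise precursor and target abundance with a
    dual-test (negative-binomial exact plus Audic-Claverie) differential
    gate on TMM-normalized counts, expectation-scored miRNA target
    prediction, and detection of 24-nt siRNA-producing loci. Includes a
    synthetic sequencing-library generator with a machine-readable truth
    ledger so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    yaml
Config/testthat/edition: 3
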