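Package: guidescreen
Title: Empirical sgRNA Library Design and Pooled CRISPR Screen Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing genome-scale CRISPR knockout sgRNA libraries
    from collections of pooled viability screens, and for analysing the
    resulting screens. Guides are selected empirically: sgRNAs with consistent
    on-target depletion across many screens are prioritised, while guides with
    outlier (off-target-like) phenotypes, problematic sequence features
    (homopolymers, BbsI sites, extreme GC) or many near-match genomic sites are
    excluded. The selected guides are assembled into two mutually exclusive
    genome-scale sub-libraries with shared controls. Screen analysis includes
    targeting-control median normalisation, log2 fold changes, a reference-set
    Bayes-factor essentiality caller with precision-recall quality gating, a
    four-component Gaussian mixture classifier of sgRNA cutting activity, and
    guide-coverage subsampling curves. A synthetic-data generator provides
    screen collections, genomes and annotations with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    yaml,
    stats,
    utils,
    Biostrings,
    IRanges,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
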