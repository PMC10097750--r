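Package: spikeshift
Title: Spike-In Anchored Detection of Global Transcriptome Shifts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects global transcriptional shifts that per-library
    normalization cannot see, by anchoring between-sample normalization to
    external spike-in controls dosed in proportion to cell number.
    Implements spike-restricted TMM normalization factors with a batch
    anchoring correction, a two-group negative-binomial exact test with
    common-dispersion estimation and Benjamini-Hochberg classification,
    gene-set intersection and Venn summaries for timecourse up/down lists,
    chi-square enrichment of gene sets in subtelomeric windows, and
    reference-genome spike-in scaling for ChIP-seq region counts. A
    negative-binomial count simulator with known global repression factors,
    spike proportions and differential-expression truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse,
    withr
Config/testthat/edition: 3
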