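Package: senoscore
Title: Marker-Anchored Senescence Signature Scoring and Regulatory-Element
    Analysis for Single-Cell and Chromatin Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterises rare senescent cell states anchored on a sparse
    marker transcript (p16/CDKN2A). Provides cell and gene quality-control
    filters and the log2((CPM/10)+1) expression transform, a Gamma-Poisson
    empirical-Bayes expression recovery with reliability-weighted
    gene-to-marker correlation ranking, marker-anchored top-N gene
    signatures scored per cell against expression-matched control gene
    sets, percentile-based cell classification, two-part (hurdle)
    differential expression with covariates and bootstrap confidence
    intervals for log2 fold changes, preranked gene-set enrichment and
    hypergeometric over-representation tests, and rule-based
    classification of promoters, enhancers, CTCF sites and TAD-boundary
    elements from chromatin peak intervals, including a simplified
    negative-binomial differential-binding test and exact PWM motif
    scanning. A synthetic-data module generates count matrices,
    regulatory landscapes and per-cell intensity tables with planted
    ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    withr,
    generics,
    stats,
    utils,
    tools,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    DESeq2
Config/testthat/edition: 3
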