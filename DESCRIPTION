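Package: hallmarksurv
Title: Pancancer Survival Analysis of Cancer Hallmark Gene Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for pancancer prognostic analysis of
    cancer hallmark genes from bulk RNA-seq. Normalizes raw counts with
    median-of-ratios size factors followed by per-sample mean rescaling,
    scores hallmark gene-set signatures as mean member expression, discovers
    each feature's strongest survival cutoff by scanning all candidate
    thresholds between the expression quartiles with Benjamini-Hochberg FDR
    control, fits univariate and multivariate Cox proportional hazards models
    with clinical covariates, computes tumor mutation burden from MAF tables,
    aggregates per-hallmark significance across tumor types with hierarchical
    clustering, and runs cutoff-keyed two-phenotype gene set enrichment
    analysis. Ships a synthetic-data generator with planted survival effects
    so the whole pipeline is exercisable without controlled-access cohorts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    fgsea,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
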