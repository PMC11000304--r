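Package: airwaysmoke
Title: Smoke-Injury Expression Dynamics, Risk Scores and Regulatory
    Genetics in Airway Epithelium
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing smoking-associated gene-expression
    dynamics in airway (nasal and bronchial) epithelium. Classifies genes
    by their post-cessation reversibility with Bayesian linear-model
    selection over a smoking-status encoding, compares dynamics between
    donor cohorts to derive smoke-injury response genes, trains
    L1-penalised logistic risk classifiers with cross-validated
    performance and stability selection, computes batch-corrected pathway
    metascores, runs covariate-adjusted cis-eQTL scans with two-step
    multiple-testing correction, tests genotype-by-smoking interactions,
    links expression-associated variants to GWAS risk loci, and scores
    transcription-factor regulon enrichment. A synthetic-cohort generator
    with planted effects makes every stage testable without access to
    controlled human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    glmnet,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    SummarizedExperiment,
    tibble,
    tidyr,
    utils,
    VariantAnnotation
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
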