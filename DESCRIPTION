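Package: ProteoBatchQC
Title: Diagnosis, Correction and Quality Control of Batch Effects in
    Quantitative Proteomics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a five-step workflow for technical-bias adjustment of
    large-scale quantitative proteomics matrices: initial assessment of
    running-order intensity structure, sample-level normalization (median,
    quantile, z-score, all missing-value aware), diagnostics of batch
    structure (PCA, hierarchical clustering, principal variance component
    analysis, feature-level trends, confounding reports), feature-level
    two-step batch correction (per-feature per-batch LOESS signal-drift
    removal followed by discrete median/mean centering or empirical-Bayes
    location-scale adjustment), and correlation-based quality control
    (replicate / within-batch / between-batch sample correlations,
    same-protein vs unrelated peptide correlations, coefficients of
    variation by abundance). Batch-coupled missingness is quantified and
    imputation is gated behind explicit, mask-tracked policies. A seeded
    synthetic-data generator reproduces the diagnosed structures (signal
    drift over running order, discrete per-feature batch shifts,
    protein-grouped peptides, spike-ins, replicate re-injections,
    batch-coupled missingness) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    sva,
    limma,
    withr,
    optparse,
    knitr,
    rmarkdown
biocViews: Proteomics, BatchEffect, Normalization, QualityControl,
    MassSpectrometry
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
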