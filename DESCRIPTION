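Package: cormclust
Title: Clustering of Regression Models for Replicated Time Course
    Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model-based gene clustering for cross-sectional, longitudinal,
    and replicated longitudinal expression designs.  Genes are clustered on
    the systematic (covariate-explained) part of their expression variation
    by fitting finite mixtures of linear models (CLM) and of linear mixed
    models (CLMM) with an EM algorithm.  Includes B-spline time-course
    design construction with per-condition fixed-effect blocks, gene-level
    random effects shared across technical replicates, BLUPs, posterior
    classification and prediction for new genes, a Lloyd K-means baseline
    together with its classification-EM mixture formulation, cluster
    diagnostics (residual summaries, eigen displays, peak-time relabelling,
    contingency-table comparison, informative-gene screening), and
    synthetic-data generators for benchmark scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    splines,
    stats,
    utils,
    yaml
Suggests:
    lme4,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
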