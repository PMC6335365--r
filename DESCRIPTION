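Package: graphfc
Title: Graph-Theoretic Functional Connectivity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Classifies subjects from resting-state ROI time series via
    graph-theoretic functional connectivity. Estimates whole-brain
    association matrices with five estimators (Spearman, percentage-bend,
    partial correlation, sparse inverse covariance, mutual information),
    binarizes them by proportional thresholding, summarises each network
    with nodal and global graph metrics, selects discriminative features
    with a sequential forward (floating) wrapper around a support vector
    machine, and evaluates and compares pipelines with stratified repeated
    cross-validation, Welch tests and Benjamini-Hochberg correction. A
    synthetic cohort generator with implanted topological group effects
    provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
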