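Package: stagemarker
Title: Stage- and Region-Resolved Transcriptomic Biomarker Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An explainable machine-learning pipeline for discovering
    stage-specific transcriptomic biomarkers of Alzheimer's disease
    progression across brain regions. Implements the full analysis chain:
    expression-matrix preprocessing (low-variance filtering, robust
    scaling, Z-score standardization, duplicate-identifier aggregation),
    three-class Braak-stage classification with gradient-boosted trees and
    SMOTE class balancing, exact tree-ensemble Shapley attribution of gene
    importance, a multi-layer gene-confidence framework (cross-validation
    stability, held-out test importance, composite validation score,
    permutation significance with Benjamini-Hochberg FDR), region-resolved
    importance aggregation, and pathway co-expression validation. Includes
    a synthetic multi-region cohort generator with planted stage- and
    region-specific signals so the whole pipeline is testable without
    controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
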