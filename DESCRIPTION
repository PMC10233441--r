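Package: hlyr
Title: Predicting Activity Limitation and Healthy Life Years from Survey Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating healthy life years without activity
    limitation from cross-sectional health-survey records. Provides a
    synthetic survey generator with a known ground-truth risk model, a
    gradient-boosted classifier of activity limitation (stratified
    splitting, recursive feature elimination, cross-validated grid
    search), an evaluation surface (AUROC with bootstrap confidence
    intervals, log loss, calibration, cost-benefit threshold selection,
    permutation importance, Monte-Carlo Shapley attribution), abridged
    life-table construction and Sullivan's method for healthy life
    years, counterfactual disease-prevalence policy simulation, and the
    HCAL individual health index with its age curve.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
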