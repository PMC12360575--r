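Package: elfrisk
Title: Subgroup-Aware Evaluation of Multimorbidity Risk Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating machine-learning risk prediction models for
    cardiovascular disease and diabetes separately in comorbid and
    non-comorbid subgroups, with a focus on the long-horizon contribution of
    early-life factors. Provides a synthetic cohort generator with known
    subgroup-specific effect structure, gradient-boosted risk models under
    stratified cross-validation, group-specific Bayes-error bounds
    (Mahalanobis, Bhattacharyya, k-nearest-neighbour), decision-curve
    analysis, performance-driver analyses (single-variable AUC, permutation
    feature importance), prediction-driver analyses (Shapley attributions,
    dual-group risk effect sizes), marker-stratified post-hoc comparisons,
    incremental feature curves, and early-life-factor contribution shares.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
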