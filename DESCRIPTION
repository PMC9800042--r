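Package: fedforest
Title: Federated Random Forests for Multi-Site Clinical Risk Classification
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training and evaluating federated random-forest
    classifiers on tabular clinical data distributed across institutions
    that cannot share patient records. Implements from-scratch gini-impurity
    decision-tree induction, proportional (largest-remainder) allocation of
    ensemble trees across sites, merging of locally trained forests into a
    single global model, and an all-combinations cross-site cross-validation
    scheme that pairs the federated model against a pooled centralized
    baseline on identical validation folds. Includes a calibrated synthetic
    two-institution cohort generator for coronary artery calcification score
    (CACS) risk classification from routine clinical features, so the full
    pipeline is testable without access to private patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
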