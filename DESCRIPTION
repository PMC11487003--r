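Package: ifptml
Title: Information-Fusion Perturbation-Theory Modelling of Longitudinal
    Anticoagulation Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling longitudinal warfarin anticoagulation
    cohorts with information-fusion perturbation-theory machine learning
    (IFPTML). Simulates visit-structured cardiac-surgery cohorts with
    pharmacogenomic covariates (CYP2C9, VKORC1), rearranges longitudinal
    records into per-visit case tables with 63-day dose and treatment-day
    windows, computes perturbation-theory features (group moving averages,
    first-order deviations, second-order Euclidean distances, reference
    prior), fits linear discriminant scoring functions and a battery of
    standard machine-learning models, and evaluates them with regression,
    predicted-bias and classification metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    jsonlite,
    withr,
    generics,
    ggplot2,
    stats,
    utils,
    caret,
    e1071,
    nnet,
    randomForest,
    pROC
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
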