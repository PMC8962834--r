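Package: ecgorigin
Title: Predicting Ventricular Arrhythmia Origin Sites from 12-Lead ECGs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A machine-learning pipeline for localizing the anatomical origin of
    idiopathic ventricular arrhythmia (PVC/VT) from single-beat 12-lead ECG
    recordings. Provides wavelet (coif5/SURE) denoising, R-peak-referenced beat
    windows, a four-level anatomical label hierarchy with partial-credit scoring,
    patient-disjoint cohort splitting with minority oversampling, an exhaustive
    window-size search, a configurable classifier registry culminating in
    extremely randomized trees, bootstrap-CI metric panels with top-k failure
    analysis, feature-importance maps, and a seeded synthetic-ECG generator so
    the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    withr,
    ranger,
    rpart,
    e1071,
    glmnet,
    nnet,
    MASS,
    xgboost,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
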