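Package: locomo
Title: Instrumented Five-Time Sit-to-Stand Assessment of Locomotive Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing locomotive syndrome stages from a single
    trunk-worn inertial measurement unit recorded during the five-time
    sit-to-stand test. Provides a synthetic cohort generator with known
    ground truth, signal preprocessing (zero-centering, resampling,
    Butterworth low-pass filtering), detection of sit-to-stand and
    stand-to-sit transitions from pitch angular-velocity minima, a
    144-metric time- and frequency-domain feature extractor (durations,
    acceleration ranges, RMS, jerk smoothness, total spectral power,
    spectral edge frequencies), and an imbalance-aware classification
    stack (SMOTE oversampling, stratified splitting, z-score scaling,
    PCA and mutual-information feature selection, grid-searched
    classifiers, and a funnel multilayer perceptron).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
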