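Package: wearpd
Title: Wearable-Sensor Detection of Parkinson's Tremor and Bradykinesia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for classifying Parkinson's
    disease tremor and bradykinesia from wrist- and hand-worn inertial
    sensors. Provides a synthetic cohort generator emulating scored motor-task
    recordings, a preprocessing chain (cubic-spline regularization, rational
    polyphase downsampling, zero-phase high-pass filtering, overlapping 5-s
    clip segmentation with a raw-sample validity rule), a 148-dimensional
    engineered feature set over five categories (time, frequency, sample
    entropy, cross-correlation, derivative), leave-one-participant-out
    random-forest evaluation with binary and weighted multiclass AUROC, and
    the sensitivity experiments comparing sensor sets, sampling rates, and
    feature-category subsets under repeated-measures ANOVA with
    Holm-Bonferroni-corrected paired tests, including a computation-time
    versus accuracy Pareto filter.
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
    ranger,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
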