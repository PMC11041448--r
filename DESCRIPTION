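Package: cevvo
Title: Continuous Evaluation of VV-ECMO Outcomes from Perfusion Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for predicting successful decannulation of patients
    supported on venovenous extracorporeal membrane oxygenation (VV-ECMO)
    from device perfusion time series combined with static clinical
    variables. Implements the full modelling pipeline: cohort file I/O,
    truncation augmentation and fixed-length standardisation of perfusion
    runs, a two-headed classifier fusing a dense static-feature encoder
    with a 1x1-convolution + LSTM temporal encoder, four reference
    classifiers, repeated patient-level cross-validation, bootstrap
    confidence intervals for AUROC and average precision, paired
    permutation tests, Platt-scaled risk grouping with Boschloo's exact
    unconditional test, a parametric generator of ECMO-like cohorts, and
    Gaussian-process synthesis of surrogate cohorts with a tunable
    temporal length scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    e1071,
    rpart
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
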