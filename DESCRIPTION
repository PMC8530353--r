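Package: ansrisk
Title: Autonomic Nerve Function and Rear-End Collision Risk in Occupational Driving
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline linking truck drivers' autonomic nerve function,
    measured by heart-rate-variability (HRV) indices, to a continuously estimated
    rear-end collision risk index. Provides windowed HRV analysis with quality
    gating and Burg maximum-entropy spectral estimation, age-referenced LF/HF
    deviation scores, rule-based driving-scene classification from 1 Hz vehicle
    telemetry, gradient-boosted near-miss classifiers that turn warning events into
    a per-20-s risk probability, logistic quantile regression of the bounded risk
    index with hierarchical AIC model selection and bootstrap inference, and
    normality-gated all-pairs shift-phase comparisons (Tukey-Kramer / Steel-Dwass).
    A fully synthetic cohort generator with known planted effect sizes makes every
    stage testable without access to fleet data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    xgboost,
    pROC,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    car
Config/testthat/edition: 3
RoxygenNote: 7.3.3
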