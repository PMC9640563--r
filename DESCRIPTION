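Package: vftrend
Title: Point-Wise Trend Analysis and Prediction of Central 10-Degree Visual Fields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how many Humphrey 10-2 visual-field examinations
    are needed to predict future point-wise sensitivities in glaucoma by trend
    analysis. Implements five per-location trend models (ordinary least-squares
    linear, exponential, quadratic, Huber M-estimator robust linear, and logistic
    regression), a rolling-origin prediction-error experiment over one- to
    three-test-ahead horizons with mean-absolute-error aggregation and a
    saturation ("number of tests required") rule, formal model comparison via
    linear mixed models with a per-patient random intercept and
    Benjamini-Hochberg multiplicity adjustment, and a synthetic longitudinal
    cohort generator with spatially correlated defects, heteroscedastic
    censored test-retest noise, and paired eyes within patients.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    readr,
    ggplot2,
    minpack.lm,
    lme4,
    lmerTest,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
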