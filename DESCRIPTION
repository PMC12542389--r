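Package: survcalib
Title: Goodness-of-Fit Calibration Tests for Survival Prediction Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assesses the calibration of predictive survival models under
    random right-censoring. Implements an Akritas-type Pearson goodness-of-fit
    test on right-censored probability-integral-transform residuals
    (A-calibration), together with the imputation-based D-calibration
    comparator, a Weibull simulation harness with three censoring schemes
    calibrated to a target censoring rate, and a Monte-Carlo engine for
    estimating type-I error and power of both tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
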