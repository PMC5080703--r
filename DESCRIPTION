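Package: valimpute
Title: Internal Validation Combined with Multiple Imputation for
    Predictive Performance Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimation of (added) predictive performance of binary-outcome
    prediction models developed on incomplete data. Combines internal
    validation (bootstrap, subsampling, cross-validation) with multiple
    imputation by chained equations using predictive mean matching, in three
    orders (Val-MI, MI-Val, MI(-y)-Val), and provides optimism-corrected,
    0.632 and 0.632+ performance estimators for AUC, Brier score, calibration
    intercept/slope, change in AUC, net reclassification improvement and
    integrated discrimination improvement, together with resampling-based
    confidence intervals and a simulation engine generating data with a
    prescribed theoretical AUC and MCAR, MAR or blockwise-MAR missingness.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
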