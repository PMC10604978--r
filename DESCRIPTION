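Package: dwgcfmri
Title: Dynamic Window-Level Granger Causality for Real-Time fMRI Decoding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts directed effective-connectivity features from ROI-level
    BOLD time series using window-level Granger causality: on every short
    sliding window an autoregressive predictor using only the target's past
    is compared against one that also uses the source's past, and the ratio
    of their out-of-sample mean squared errors is thresholded against a
    surrogate-calibrated null. The thresholded F values feed a motor-imagery
    classifier suite (naive Bayes, polynomial and RBF support vector
    machines, gradient boosting) evaluated with block-stratified K-fold
    cross-validation, confusion matrices, Cohen's kappa and per-TR
    decoding-accuracy curves. A synthetic-data module simulates block-design
    runs with condition-switched vector-autoregressive coupling, double-gamma
    hemodynamic convolution and rendered NIfTI volumes with known ground
    truth, and a streaming harness replays runs volume-by-volume to emulate
    the per-TR real-time loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    lmtest,
    yaml
Config/testthat/edition: 3
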