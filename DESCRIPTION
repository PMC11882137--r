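Package: hetriage
Title: Hematoma Expansion Annotation and Expert-Review Triage for Paired Head CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for generating ground-truth hematoma-expansion (HE)
    annotations from paired baseline/follow-up head CT volumes. Implements a
    synthetic paired-CT phantom generator with a calibrated segmentation
    error model, the standard head-CT preprocessing chain (intensity-threshold
    skull stripping, brain window/level normalization, resampling to a common
    grid), two interchangeable hematoma segmenters (a small trainable 3-D
    U-Net and a deterministic oracle-perturbation engine), absolute-HE
    volumetry and binarization at the 3/6/9/12.5 mL thresholds, three HE
    scorers (direct volume difference, a four-input convolutional classifier,
    and a CNN-feature RBF-SVM hybrid), segmentation and classification
    metrics (Dice, Hausdorff distance, ROC/AUC with bootstrap confidence
    intervals), and sensitivity/specificity-targeted operating-point
    calibration with expert-review triage accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    RNifti,
    e1071,
    yaml,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
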