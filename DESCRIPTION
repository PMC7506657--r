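Package: gaitstep
Title: Gait Activity Classification from Step-Segmented Inertial Sensor Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of five gait activities (walking on level ground,
    up/down an incline, up/down stairs) from step-segmented triaxial
    accelerometer and gyroscope recordings. Provides three data treatments for
    class imbalance (original unbalanced data, subsampling to the minority
    class, and augmentation to the majority class via five time-series
    operators), a shallow pipeline based on statistical step features with
    four classifiers under stratified cross-validation, a deep pipeline that
    encodes step signals as three-channel Gramian Angular Field images
    classified by a compact convolutional network, a shared evaluation-report
    schema, and a synthetic gait generator with controllable class separation
    and imbalance for end-to-end testing without access to restricted gait
    datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    e1071,
    jsonlite,
    Rcpp,
    rpart,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
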