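Package: rowimu
Title: Inertial Motion Capture and Stroke Analysis for Rowing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for capturing and analysing rowing motion from body-worn
    9-degree-of-freedom inertial measurement units. Implements magnetometer
    hard/soft-iron calibration by ellipsoid fitting, a gradient-descent
    quaternion orientation filter fusing gyroscope, accelerometer and
    magnetometer streams, rigid-segment skeleton reconstruction with joint
    flexion angles, stroke-cycle detection and stroke-quality metrics,
    windowed time/frequency feature extraction, and phase/proficiency
    classification with neighbourhood component analysis feature selection.
    A built-in rowing-motion simulator with an inverse sensor model provides
    ground-truth data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite,
    ggplot2,
    rlang,
    generics,
    stats,
    utils,
    e1071,
    rpart,
    xgboost,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
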