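Package: imugait
Title: Joint Kinematics and Vertical Ground Reaction Force Estimation
    from Wearable Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for wearable-IMU gait analysis: identification of
    hip, knee and ankle hinge-joint geometry (flexion/extension axis
    directions and joint-centre offsets) from raw gyroscope and
    accelerometer streams by constrained least squares; drift-free
    flexion/extension angle estimation by complementary-filter fusion
    of gyroscope integration and accelerometer projection; gait-event
    detection and gait-cycle normalisation; estimation of
    body-weight-normalised vertical ground reaction force (vGRF) with
    random-forest and feedforward neural-network regressors; and an
    evaluation suite (RMSE, NRMSE, Pearson correlation, characteristic
    vGRF peak magnitude and timing errors, permutation feature
    importance). A synthetic-data module simulates rigid hinge-joint
    motion and multi-speed treadmill gait with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    minpack.lm,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
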