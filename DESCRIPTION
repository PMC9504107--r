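Package: posturekit
Title: Wearable IMU Posture Capture, Joint-Angle Reconstruction and
    Work-Task Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for whole-body posture capture from body-worn 9-axis
    MARG (magnetic, angular-rate, gravity) sensor nodes. Implements
    hard-iron/ellipsoid magnetometer calibration, gyroscope bias
    estimation, static attitude initialisation from gravity and the
    geomagnetic field, gradient-descent quaternion sensor fusion, a
    pelvis-rooted 15-segment rigid-body model with forward kinematics
    and joint flexion angles, sliding-window time/frequency feature
    extraction from joint-angle series, and multi-classifier evaluation
    of seated work-task recognition. A built-in MARG simulator generates
    ground-truth motion and corrupted sensor traces so the whole
    pipeline is testable end to end without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    caret,
    e1071,
    jsonlite,
    nnet,
    pROC,
    pracma,
    randomForest,
    rpart,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
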