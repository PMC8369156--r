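Package: adaptahrs
Title: Adaptive Madgwick Orientation Filtering for Sports Movement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Orientation estimation from 9-axis inertial measurement units
    (IMUs) in situations that violate the assumptions of earth-frame-based
    attitude estimates, such as wheelchair sports with sustained linear
    accelerations and nearby ferromagnetic material. Implements the
    gradient-descent complementary (Madgwick) filter together with an
    adaptive extension in which the earth-frame correction gain switches
    per sample between a large and a small value, driven by a classifier
    that predicts from raw IMU signals whether the accelerometer- and
    magnetometer-based orientation estimate is currently trustworthy.
    Includes marker-cluster and IMU pre-processing (hard-iron correction,
    spline resampling, gap interpolation, cross-correlation time
    synchronization), helical-angle trunk-inclination kinematics, trust-label
    generation, leave-one-subject-out classifier training and selection,
    correction-gain grid search, Bland-Altman style agreement analysis, and
    a seeded two-sensor session simulator with ground-truth orientations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp,
    ranger,
    rpart,
    e1071,
    yaml,
    jsonlite,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
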