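Package: gaitkinetics
Title: Predicting Whole-Body Running Kinetics from a Sacral Accelerometer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for estimating peak vertical ground reaction force,
    vertical impulse, and ground contact time during running from a single
    sacral-mounted accelerometer. Implements zero-lag Butterworth filtering,
    countermovement-jump based clock synchronization, threshold-based stance
    detection on force and acceleration channels, acceleration-based vertical
    ground reaction force estimation via Newton's second law, and predictive
    modelling with ordinary least squares regression and 500-tree quantile
    regression forests under subject-held-out evaluation. Includes a
    biomechanically consistent gait simulator that generates paired treadmill
    force and sacral acceleration recordings with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
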