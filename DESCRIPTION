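Package: drinksense
Title: Drinking-Gesture Recognition and Fluid-Intake Volume Estimation
    from Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A hierarchical fluid-intake assessment pipeline for tri-axial
    inertial (accelerometer + gyroscope) recordings of drinking events,
    covering both a wrist-worn and a smart-container (cup-mounted) sensor
    placement.  Sliding-window statistical features feed an RBF-kernel
    support vector machine that recognizes the five drinking gestures
    (grasp, pre-sip, sip, post-sip, release); a run-length label
    postprocessor corrects isolated misclassified fragments; inclination
    and duration features of the recognized sip segment drive support
    vector regression models (general and sip-size-dependent) for fill
    level and intake volume.  Includes a seeded synthetic dual-placement
    session generator that emulates a 12-participant protocol (7 fill
    levels x 3 sip sizes x 4 repetitions), leave-one-subject-out
    evaluation with standard classification and regression metrics, a
    window-size/overlap grid study, and plain-text dataset serialization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
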