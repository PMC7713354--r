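Package: gaitfall
Title: Simulation and Analysis of Phase-Gated Gait Perturbation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying trip- and slip-recovery biomechanics with a
    movable perturbation platform: real-time gait-phase estimation from a
    thigh IMU (bandpass filtering, unit-sine Levenberg-Marquardt fitting,
    phase-portrait analysis), phase-segment-gated perturbation triggering,
    a kinematic simulation of the differential-drive subject follower,
    stride segmentation with 60/40 stance/swing time normalization, and
    one-dimensional statistical parametric mapping (repeated-measures
    ANOVA fields, random-field-theory and permutation thresholds,
    suprathreshold clusters, Bonferroni-corrected post-hoc t fields).
    Includes a synthetic gait generator so every stage is testable without
    human-subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
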