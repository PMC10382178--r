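Package: compsense
Title: Detection of Compensatory Strategies in Upper-Body Movement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects compensatory movement strategies in upper-body motion from
    joint kinematics and dynamics. Provides energy-based per-joint features
    (angular jerk, power, effort, torque rate) with cumulative-average
    aggregation, automatic motion-primitive segmentation by end-effector
    velocity zero-crossings (offline and streaming), interpretable linear
    classifiers (logistic regression and linear support vector machine) with
    per-joint weight-feature attribution of the compensating degrees of
    freedom, class-balanced evaluation with leave-one-participant-out
    cross-validation, and a seeded synthetic motion generator emulating a
    healthy-versus-acted-compensation study design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    glmnet
Config/testthat/edition: 3
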