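Package: swilift
Title: Size-Weight Illusion Scoring and Lift Kinematics for Real Versus
    Virtual Object Lifting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing size-weight illusion (SWI) experiments in
    which participants lift and rate the heaviness of objects in physical
    and virtual environments. Provides a synthetic-data generator emulating
    a counterbalanced two-condition lifting study (magnitude-estimation
    heaviness ratings, 90 Hz wrist/object tracker streams, presence
    questionnaires); reach and lift kinematic extraction (zero-phase
    dual-pass Butterworth smoothing, velocity-threshold segmentation,
    maximum reach/lift velocity and timing); per-participant SWI scores
    from heaviness-rating regressions on object mass and volume; and the
    accompanying statistical toolkit (winsorisation, paired tests with
    Cohen's d_z, within-subjects ANOVA with partial eta squared,
    Jeffreys-Zellner-Siow Bayes factors by adaptive quadrature, and
    noncentral-t power analysis for paired designs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
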