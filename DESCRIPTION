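Package: aida
Title: Artificial Intelligence Dystocia Algorithm for Transverse Fetal Head Position
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classification and evaluation pipeline for labor dystocia risk in
    transverse fetal head position from intrapartum ultrasound. Implements the
    AIDA (Artificial Intelligence Dystocia Algorithm) scheme: traffic-light
    color coding of four geometric parameters (angle of progression,
    head-symphysis distance, midline angle, asynclitism degree) against
    configurable thresholds, the 0-4 ordinal AIDA class, clock-face and
    rotation-angle geometry of fetal occiput position with ISUOG sector and
    midline-angle stratum assignment, seeded train/test machine-learning
    outcome prediction (support vector machine, random forest, multilayer
    perceptron), a statistical evaluation toolkit (confusion-matrix metrics,
    Wilson score intervals, McNemar paired tests, Pearson correlation, AUC),
    stratified descriptive outcome analysis, a packaged 66-case reference
    cohort, and a synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    MASS,
    e1071,
    randomForest,
    nnet
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
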