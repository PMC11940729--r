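Package: oculocog
Title: Multimodal Oculomotor and Cognitive Assessment for MCI Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates and analyses multimodal cognitive screening sessions
    combining four oculomotor paradigms (pro/anti-saccades, smooth pursuit,
    memory-guided saccades, predictive saccades) with Stroop and working-memory
    span tasks. Provides a synthetic 60 Hz gaze generator with group-dependent
    oculomotor phenotypes, velocity-threshold saccade detection, extraction of
    a canonical 39-feature participant representation (31 eye-movement plus 8
    behavioral features), a one-dimensional convolutional neural network
    classifier with fully connected, support vector machine and random forest
    baselines, and a repeated-holdout evaluation protocol with per-class hit
    rates, feature-set ablations and ROC analysis for classifying mild
    cognitive impairment against elderly and young controls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    jsonlite,
    e1071,
    randomForest
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
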