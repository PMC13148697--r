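Package: seqreplay
Title: Sequential Learning with Experience Replay for Joint Diagnosis
    and Prognosis from Medical Images
Version: 0.1.0
Authors@R:
    person("Seqreplay", "Maintainers", email = "maintainers@seqreplay.dev",
           role = c("aut", "cre"))
Description: A desk-scale, fully reproducible harness for studying
    continual-learning strategies that couple a data-rich diagnosis task
    (ordinal severity grading of single images) with a data-scarce
    prognosis task (binary progression within a fixed horizon). Provides
    a calibrated synthetic image cohort generator with a known latent
    disease model, leakage-safe patient-level cross-validation with a
    pretraining holdout, six training regimes for a small two-headed
    convolutional network (dedicated diagnosis reference, single-task
    prognosis from random or diagnosis-pretrained weights, single-cohort
    multitask, concurrent multitask, diagnosis-pretrained multitask, and
    sequential learning with experience replay), and a complete
    evaluation suite: AUROC, AUPRC, balanced accuracy, macro/micro
    AUROC, Youden-index operating points, fold ensembling, the DeLong
    test for correlated ROC curves, confusion matrices, and subgroup and
    catastrophic-forgetting analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
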