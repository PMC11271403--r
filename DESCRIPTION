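Package: afwear
Title: Wearable Heart-Rate Analytics for Rate-Control Trials in Atrial
    Fibrillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis pipeline for randomized rate-control
    trials instrumented with consumer wearables. Generates synthetic two-arm
    cohorts of per-minute heart-rate and step-count streams with circadian
    structure, activity coupling and device-off missingness; pools streams to
    per-minute series and weekly summaries; compares treatment arms with a
    Gaussian generalized estimating equation under an exchangeable working
    correlation with robust (sandwich) standard errors; learns a
    self-supervised one-dimensional convolutional network by discriminating
    original from cross-patient channel-scrambled windows, with missingness
    encoded as a third input channel; and predicts end-of-trial NYHA
    functional class from the learned embeddings with ridge-penalized
    logistic regression, evaluated by F1 score, AUROC and bootstrap
    confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
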