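Package: rtrisk
Title: Radiotherapy Toxicity and Secondary Cancer Risk Modelling for
    Matched Breast-Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for modelling radiation-induced toxicity in breast-cancer
    radiotherapy cohorts described by dose-volume histograms (DVHs).
    Implements propensity-score caliper matching of treatment arms,
    L1-penalized logistic (LASSO) selection of dominant dosimetric risk
    factors with cross-validation and the one-standard-error rule, maximum
    likelihood fitting of the Lyman-Kutcher-Burman normal tissue
    complication probability (NTCP) model with profile-likelihood
    confidence intervals and standard performance metrics (AUC,
    Hosmer-Lemeshow, scaled Brier score, calibration slope), and Schneider
    organ-equivalent-dose / excess-absolute-risk models of secondary cancer
    induction for organs at risk.  Includes a synthetic cohort generator
    with known ground truth and an end-to-end analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
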