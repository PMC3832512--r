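Package: triagedx
Title: Decision-Analytic Triage for High-Specificity, Low-Sensitivity
    Diagnostic Tests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for deciding which candidate patients should receive an
    expensive confirmatory diagnostic test. Posterior probabilities of a
    positive test outcome are estimated from pre-test data by K-nearest
    neighbour classification or logistic regression and evaluated by
    leave-one-out cross-validation. The package provides ROC, likelihood-ratio
    and binormal (d', d_a) summaries, loss-matrix based decision thresholds,
    expected-loss curves for clinical and screening-study designs, the
    net-benefit equivalence of decision-curve analysis, and an exhaustive
    search for high-yield rectangular regions in two-dimensional predictor
    spaces. The worked example is the glycerol test for Meniere's disease,
    where the predictors are pure-tone audiogram thresholds and the outcome
    criterion is an aggregate threshold reduction (ATR) of at least 30 dB;
    seeded synthetic cohort generators emulating that study ship with the
    package.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
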