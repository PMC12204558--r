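Package: sptbcv
Title: Leakage-Safe Cross-Validated Prediction of Spontaneous Preterm Birth
    from Two-Timepoint Maternal Blood Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and stress-testing transcriptomic classifiers
    of spontaneous preterm birth from paired (second and third trimester)
    maternal whole-blood expression profiles. Provides a synthetic two-timepoint
    case-control cohort generator with known ground truth, gene filtering and
    repeated-measures moderated differential expression with five
    timepoint-by-outcome contrasts, stepwise additive feature selection scored
    by nested cross-validated AUROC, five prediction model families (logistic
    regression, ridge, elastic net, random forest, multilayer perceptron), a
    repeated stratified cross-validation pipeline with external validation, and
    two methodological probes: a leakage-prone execution mode (differential
    expression before data splitting) and a permuted-label overfitting control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
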