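Package: fdosmbench
Title: Diagnostic Model Benchmarking with Fuzzy Decision by Opinion Score Ranking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking multiclass diagnostic classifiers on
    rheumatic and autoimmune disease cohorts and ranking them by the fuzzy
    decision by opinion score method (FDOSM). Includes a synthetic clinical
    cohort generator with configurable class-conditional marker profiles and
    missing-completely-at-random masking, mean/mode imputation, categorical
    encoding, an implementation of ADASYN adaptive synthetic oversampling, a
    twelve-model benchmark harness, a seven-metric evaluation suite (macro
    precision/recall/F-score, Cohen's kappa, Hamming loss, Matthews
    correlation, accuracy) with overfitting and balanced-versus-unbalanced
    difference statistics, triangular-fuzzy-number aggregation of expert
    linguistic opinion matrices into group rankings, and perturbation-based
    local and global model explanations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    withr,
    xgboost,
    randomForest,
    ranger,
    e1071,
    rpart,
    nnet,
    class,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    caret,
    pROC
Config/testthat/edition: 3
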