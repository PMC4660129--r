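Package: ehrade
Title: Adverse Drug Event Detection from Structured Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for detecting adverse drug events (ADEs)
    from structured electronic health record event logs. Builds case/control
    cohorts from ICD-10 concept-hierarchy similarity, derives patient feature
    matrices from clinical codes (hierarchy-level aggregation of ICD-10 and
    ATC codes) and repeated clinical measurements (mean, standard deviation,
    slope, existence, count), ranks features by information gain, evaluates
    nine standard classifiers under repeated stratified cross-validation with
    accuracy and AUC, and compares configurations across datasets with the
    Friedman test and the Bergmann-Hommel post-hoc procedure. Includes a
    synthetic EHR generator with plantable signal so every stage is testable
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    rpart,
    ranger,
    e1071,
    glmnet,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
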