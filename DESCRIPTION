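Package: rfrs
Title: Random Forests Relapse Score for Breast Cancer Prognosis
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds and applies the Random Forests Relapse Score (RFRS), a
    prognostic classifier of 10-year relapse for node-negative, ER-positive,
    HER2-negative breast cancer. Provides the full pipeline from a normalized
    expression matrix and clinical table to per-patient relapse-likelihood
    reports: duplicate-sample removal, array-based ER/HER2 status calling via
    Gaussian-mixture cutoffs, probe filtering, study-balanced cohort splitting,
    out-of-bag random-forest scoring, compaction of the full model into
    17-gene and 8-gene signatures with ranked alternate genes via k-means
    redundancy clustering, mixture-model risk-group thresholds,
    prevalence-matched down-sampling calibration of per-group relapse rates, a
    loess score-to-likelihood curve, Kaplan-Meier log-rank trend testing, and
    cross-platform signature mapping. Ships a synthetic multi-study cohort
    generator so every stage is exercisable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    mclust,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
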