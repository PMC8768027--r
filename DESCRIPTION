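Package: tofanomaly
Title: Outlier Detection for Acceleromyographic Train-of-Four Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates labelled train-of-four (TOF) acceleromyographic
    recordings, extracts basic and pattern-engineered waveform features
    from the combined acceleration/angular-velocity envelope, fits
    cost-sensitive L2-regularised logistic regression classifiers for
    imbalanced outlier detection, and reproduces a full evaluation
    protocol: stratified train/test splitting, stratified k-fold grid
    search, precision/recall/F1/ROC-AUC with bootstrap confidence
    intervals, learning curves, and paired Wilcoxon model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
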