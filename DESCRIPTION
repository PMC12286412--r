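Package: fwfoot
Title: Footballer Workload Footprint Matrices and Injury-Risk Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models athlete external workload as per-player variables-by-events
    matrices (the Footballer Workload Footprint), generalizes acute and chronic
    workload into rolling cumulative and differential feature blocks over
    configurable window sets, implements the classical coupled, uncoupled and
    EWMA acute:chronic workload ratios, and provides the full imbalanced
    binary-classification evaluation pipeline used to compare them: pre-match
    undersampling, robust-PCA outlier removal, temporal train/test splitting,
    SMOTE oversampling, unstandardized PCA, repeated stratified cross-validation
    over eight classifier families, imbalance-aware metrics with t-based
    confidence intervals, permutation testing and a bias-variance decomposition.
    Includes a synthetic multi-player season generator with a planted
    spike-driven injury hazard so the whole pipeline is testable without
    proprietary club data, and heatmap rendering of the workload matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    MASS,
    class,
    e1071,
    nnet,
    randomForest,
    rpart,
    ggplot2,
    patchwork
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
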