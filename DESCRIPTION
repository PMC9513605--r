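Package: pumda
Title: Positive-Unlabeled miRNA-Disease Association Prediction with
    Clustering-Based Negative Sampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts miRNA-disease associations from a curated association
    list under the positive-unlabeled setting. Represents each miRNA-disease
    pair by integrated similarity features (MeSH-style disease semantic
    similarity combined with Gaussian interaction profile kernels), builds a
    low-contamination negative sample set by mini-batch k-means clustering of
    the total pair set and harvesting the clusters least contaminated by known
    positives, and classifies pairs with a soft-voting ensemble of tree
    learners over balanced, feature-selected training subsets. Includes a
    synthetic data generator with planted structure, five-fold
    cross-validation, standard classification metrics, and a
    leave-one-disease-out case-study ranker.
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
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
Suggests:
    cluster,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
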