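Package: hiermc
Title: Hierarchical Meta-Classification for Imbalanced Disease-Stage Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies patient visit records into chronic kidney disease
    severity stages (3, 4, 5) under severe class imbalance using hierarchical
    meta-classification: the majority class is partitioned into balanced
    subsets, an ensemble of base classifiers re-represents each record as a
    vector of predicted labels, a categorical naive-Bayes meta-classifier
    separates the majority class from the combined minority classes, and a
    refinement classifier splits the combined class into its constituents.
    Includes a synthetic imbalanced EHR-cohort generator, temporal
    train/test splitting, per-class evaluation metrics, and a comparison
    harness against one-against-all baselines, random under-sampling, and
    SMOTE over-sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
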