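Package: progsig
Title: Comparison of Single-Gene, Gene-Set and Network-Based Prognostic
    Gene Expression Signatures
Version: 0.1.0
Authors@R:
    person("progsig", "developers", email = "progsig@example.org",
           role = c("aut", "cre"))
Description: A pipeline for building and comparing prognostic gene
    expression signatures from two-class (good versus poor prognosis)
    cohorts. Implements five feature selection strategies spanning the
    single-gene (empirical-Bayes moderated t), gene-set (median expression
    of protein-protein interaction hub gene-sets) and network-based
    (PageRank-style survival-correlation ranking, differential hub
    correlation, and a between/within sum-of-squares correlation ratio)
    families, three classifiers (diagonal linear discriminant analysis,
    a bagged decision forest and a linear support vector machine) under a
    common train/predict contract, and repeated stratified 5-fold
    cross-validation with strictly in-fold feature selection. Evaluation
    covers overall and class-specific error, feature selection stability
    (mean pairwise top-k overlap across folds) and patient-level accuracy.
    A synthetic data generator plants differential expression, differential
    median expression and differential correlation signal with ground-truth
    labels so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
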