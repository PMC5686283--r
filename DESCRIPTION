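Package: fhrbench
Title: Benchmarking pH-Based Fetal Heart Rate Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable benchmark pipeline for classifying intrapartum fetal
    heart rate (FHR) recordings against umbilical-artery pH outcomes
    (abnormal iff pH <= 7.05). Provides artifact rejection with monotone
    Hermite gap interpolation, a 54-variant multi-domain feature bank
    (FIGO-style macroscopic descriptors, beat-to-beat variability indices,
    Welch band energies, entropies, fractal dimensions, detrended
    fluctuation analysis, Poincare geometry), exact Mann-Whitney AUC feature
    ranking under leave-out resampling, a from-scratch cost-weighted
    least-squares support vector machine, an imbalance-aware nested
    stratified cross-validation protocol with imbalance-robust metrics, a
    PCA + SMOTE + minimum-Mahalanobis-distance baseline comparator, and a
    synthetic FHR generator so every stage is testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
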