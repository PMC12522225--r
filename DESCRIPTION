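Package: cfMotifScreen
Title: Multi-Omics cfDNA End-Motif and Protein-Marker Screening Models for
    Esophageal Squamous Cell Carcinoma
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements an end-to-end early-detection analysis for esophageal
    squamous cell carcinoma (ESCC) and its precancerous lesions from plasma
    cell-free DNA (cfDNA) fragmentomics and serum protein markers. Aligned
    cfDNA fragments are profiled into a 4-mer terminal end-motif matrix
    (count, ratio-to-average and Z-score representations held in a
    SummarizedExperiment-derived container), differential motifs are selected
    by two-sample t-tests, reduced by principal component analysis, and fed
    with tumour protein markers into random-forest classifiers chosen by
    recursive feature elimination under stratified cross-validation.
    Screening-oriented evaluation provides ROC/AUC with DeLong variance,
    paired DeLong comparison of correlated AUCs, Youden-index thresholds,
    Wald confidence intervals for sensitivity and specificity by lesion
    subgroup, and baseline-comparability statistics. A seeded synthetic
    cohort generator with planted motif and protein effects makes every
    stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    Rsamtools,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
biocViews: Classification, Sequencing, FeatureExtraction, Software
RoxygenNote: 7.3.3
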