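Package: BreastSubtypes
Title: Microarray-Based Molecular Subtyping of Breast Cancer with
    Treatment-Response Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovers and validates molecular subtypes of breast cancer
    from log2 expression matrices. Implements probe-set selection anchored
    on pivotal genes (linear and quadratic correlation with intensity,
    range and kurtosis filters), two-step k-means subtype discovery with
    nearest-centroid cross-dataset classification, bimodal cut-point
    calling for ER/PR/HER2 marker status, Oncotype-style recurrence score
    and MammaPrint-style correlation risk scores, an exact r x c Fisher
    (Freeman-Halton) test via a log-space network algorithm, Kaplan-Meier
    and log-rank survival comparisons, permutation-based cross-dataset
    subtype concordance, and a synthetic cohort generator with planted
    subtype, marker and survival structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    limma,
    survival,
    mclust,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
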