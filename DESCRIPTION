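Package: tfanet
Title: Transcription-Factor Activity Networks from Expression Compendia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers gene-regulatory networks in three steps: mutual-information
    screening of transcription factor (TF)-target pairs with a Gaussian-kernel
    estimator and a fitted t-distribution null; conditional-mutual-information
    detection of modulator-TF-target triplets on expression-conditioned sample
    splits with permutation significance; and a hierarchical linear-Gaussian
    model that estimates hidden TF activity by hard-assignment EM with a
    sparse (L1/ADMM) M-step. Includes three-layer network assembly and
    topology statistics, a bootstrap test of activity-based versus mRNA-based
    mutual information, a context-specific rewiring analysis, and a synthetic
    data generator with known ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    igraph,
    MASS,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
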