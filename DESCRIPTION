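Package: icdaug
Title: Silver-Standard Data Augmentation and Hierarchical Evaluation for
    Low-Resource ICD-10 Coding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying synthetic-document data augmentation of
    low-resource ICD-10 code families in automated medical coding. Provides
    an ICD-10-like code hierarchy model, coded-corpus input/output and label
    population statistics, selection of low-resource code families,
    construction of silver-standard generation requests (cloning, label
    dropping, zero-shot sibling substitution, temperature policy), a
    pluggable document generator with a deterministic built-in template
    generator, a convolutional per-label-attention multi-label coder,
    flat and hierarchical evaluation (set-based and count-preserving),
    weak hierarchical confusion matrices for within-family versus
    out-of-family error analysis, Fleiss' kappa rater agreement, and a
    synthetic corpus simulator with frequent, few-shot, and zero-shot
    label strata so the whole pipeline runs end to end on generated data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
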