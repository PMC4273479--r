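Package: aluscancnv
Title: Read-Depth Copy-Number Variation Calling for Sparse Alu-Anchored
    Capture Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-level read-depth analysis of sparse, Alu-anchored capture
    sequencing data. Calls localized single-window copy-number variants with a
    Geary-Hinkley transformation of read-depth ratios against a paired control
    or a pooled reference template, identifies recurrent variants across a
    cohort with an exact Poisson-binomial tail test, calls extended
    multi-window variants with GC-corrected Z scores and circular binary
    segmentation, and selects discriminative CNV features for sample
    classification with correlation-based feature selection and naive Bayes
    cross-validation. Includes a synthetic-data generator emulating the sparse
    coverage regime of inter-Alu capture so every stage can be exercised with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    pracma,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
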