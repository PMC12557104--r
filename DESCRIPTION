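Package: niptsynth
Title: Synthetic Cell-Free DNA Cohorts and Aneuploidy Classifiers for NIPT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Generates synthetic negative and positive non-invasive prenatal
    testing (NIPT) datasets and trains aneuploidy classifiers on them. Synthetic
    negatives are produced either by merging and subsampling real FASTQ read
    sets with exact fetal-fraction bookkeeping, or by simulating per-chromosome
    read-count profiles with GC-tilted chromosome proportions and a Y-chromosome
    read-misassignment background. Synthetic positives for trisomy 13/18/21 and
    the sex-chromosome aneuploidies XO, XXX, XXY and XYY are derived from
    negatives by closed-form read-count arithmetic combined with regression
    models of the Y-chromosome read count. Logistic-regression classifiers
    trained on the synthetic cohorts are evaluated against a conventional
    z-score baseline on prevalence-stratified evaluation sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
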