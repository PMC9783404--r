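Package: teshape
Title: mRNA Secondary Structure and Translation Efficiency Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline linking transcriptome-wide RNA structure
    probing data (icSHAPE, DMS-seq) to translation efficiency measured by
    Ribo-seq/RNA-seq. Computes RPKM-based translation efficiency and
    high/low-TE classes, extracts sequence and structural feature sets
    (including 60-bin length-normalised metagene reactivity profiles, CDS-head
    reactivity and in-silico folding energies), trains and compares random
    forest and elastic-net classifiers over repeated stratified splits with
    cross-validated tuning, aggregates grouped and per-bin feature
    importances, and performs per-bin Kolmogorov-Smirnov differential
    reactivity tests with false-discovery-rate control. Ships a fully
    specified synthetic-data generator with plantable structure-TE coupling
    so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
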