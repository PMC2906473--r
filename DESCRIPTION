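Package: gmycbar
Title: Single-Threshold GMYC Species Delimitation with Character-Based
    Barcode Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits the null single-coalescent and single-threshold general
    mixed Yule coalescent (GMYC) branching models to ultrametric trees,
    tests them against each other by likelihood ratio, extracts
    putative-species partitions with 2-log-likelihood confidence sets, and
    assigns query barcode sequences (including degraded ones) to delimited
    entities via pure diagnostic characters. Includes the sequence-QC steps
    used around such analyses (TN93 distances, substitution-saturation
    screens, RY recoding, base-composition homogeneity tests, mitochondrial
    translation screens), consensus calling and cytosine-deamination damage
    profiling for cloned ancient-DNA amplicons, and simulators for
    Yule-coalescent trees, alignments and damaged clone sets with
    machine-readable truth ledgers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix
Config/testthat/edition: 3
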