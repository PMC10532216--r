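Package: effectorscan
Title: Biotype-Specific Salivary Effector Candidate Discovery for
    Sap-Sucking Insects
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-omics pipeline for identifying biotype-specific
    salivary effector candidates in aphids and other sap-sucking insects
    with two virulence types. Provides negative-binomial differential
    expression testing between biotypes, signal-peptide and transmembrane
    screening of differentially expressed genes, in-silico tryptic
    digestion with iBAQ-style label-free quantification and parsimony
    protein-group inference for salivary proteomes, a translated homology
    screen of published effectors, a combined proteome-by-transcriptome
    candidate strategy with qPCR (2^-ddCt) validation, and a seeded
    synthetic-data generator with planted ground truth for end-to-end
    validation.
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
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
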