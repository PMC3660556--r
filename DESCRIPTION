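Package: melascope
Title: Whole-Exome Mutation and Copy-Number Characterization of Melanoma Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for characterizing somatic coding
    mutations and DNA copy-number alterations in small tumor cohorts profiled
    by whole-exome sequencing and SNP arrays, modelled on the analysis of six
    metastatic melanoma cell lines. Implements the high-quality SNV filter
    cascade (depth, call quality, non-reference allele fraction, known-site,
    coding and blacklist filters), WES-versus-array genotype concordance
    calibration of the minimum read depth, the strand-collapsed substitution
    spectrum and non-synonymous/synonymous statistics, screening against
    cancer mutation catalogues and a curated melanoma gene list, gene-level
    copy-number calls including homozygous deletions and compound
    mutation-plus-loss events, recurrent and de novo gene discovery, and a
    fully specified synthetic cohort generator with truth tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    vcfR,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
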