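Package: kernelrow
Title: Genetic Architecture and Genomic Prediction of Maize Kernel Row Number
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for dissecting a quantitative maize ear trait
    (kernel row number) in a structured inbred panel and biparental families:
    synthetic-data generation with subpopulation structure and tunable linkage
    disequilibrium, per-environment phenotype summaries with across-environment
    BLUP and repeatability, single-SNP GLM and mixed-linear-model association
    scans with Li-Ji effective-test correction and structure-adjusted variance
    explained, LD-block tagSNP banking, RR-BLUP whole-genome prediction
    experiments over marker sets, training sets and validation populations
    (including hybrids), F2:3 composite interval mapping by Haley-Knott
    regression with gene-action classification, and sliding-window QTL hotspot
    and co-localization analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lme4,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
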