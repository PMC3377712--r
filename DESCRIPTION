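Package: placemass
Title: Placement-Based Analysis of Vaginal Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for phylogenetic-placement analysis of
    16S rRNA amplicon surveys of the vaginal microbiota. Covers quality
    filtering and demultiplexing of barcoded pyrosequencing reads, curation of
    a niche-specific reference package (mislabel screening, primary and
    representative sequence selection, neighbor-joining stand-in tree),
    placement-based taxonomic classification with compound naming, tree-mass
    community comparison (Kantorovich-Rubinstein earth-mover distance, squash
    clustering with bootstrap support, edge principal components analysis,
    phylogenetic island clustering), ecological statistics (Shannon diversity,
    Chao1 richness, abundance trimming, co-occurrence analysis), and the two
    association models used to relate the microbiota to host covariates:
    zero-inflated negative binomial likelihood-ratio tests for race-by-BV
    interactions and cross-validated elastic-net models of Amsel clinical
    signs. A fully seeded synthetic-data generator emulates the statistical
    structure of such studies so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    phangorn,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    glmmTMB,
    glmnet,
    phangorn,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
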