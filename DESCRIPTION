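Package: modnet
Title: Disease-Module Detection and Network Statistics for Cohort Variant Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline from a cohort variant table to a
    disease module on a protein-protein interaction network. Implements
    high-confidence variant filtering, odds-ratio screening against background
    population allele frequencies, gene-level aggregation and recurrence
    counting, seed-set construction, hypergeometric connectivity significance
    with iterative DIAMOnD module expansion, gene-set fold enrichment with
    cumulative hypergeometric tests, edge-Jaccard module similarity, and
    permutation nulls from random seed sets. Ships a synthetic-data generator
    (scale-free interactome with planted dense modules, cohort variant tables
    with attributable decoy records, enriched annotation collections) so every
    stage is testable against known ground truth.
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
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
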