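Package: rankmap
Title: Rank-Based Expression Signature Maps for Phenotype Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds per-sample rank-based transcriptional signatures from
    expression profiles (designed around circulating miRNA panels), computes
    an enrichment-score similarity between every pair of signatures, draws a
    sample similarity map from the smallest distances, partitions it into
    communities, and diagnoses samples of unknown phenotype by a
    neighbour majority vote. Includes a virtual-control differential
    transform, Mann-Whitney feature preselection, a seeded two-group
    synthetic cohort generator, GraphML export for external viewers, and
    tidy()/glance()/autoplot() methods for the fitted map.
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
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
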