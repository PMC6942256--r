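Package: coabnet
Title: Gut Microbiome Co-Abundance Networks and Taxonomic Imbalance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for multi-study gut microbiome abundance tables:
    lineage parsing and rank-level aggregation, relative-abundance
    normalisation, richness, Shannon diversity and analytic rarefaction,
    fold-change classification of taxa between disease conditions, and a
    thresholded Pearson family-family co-abundance network with an
    intra-phylum connectivity statistic, a uniform random-graph null model,
    and condition-specific subnetwork extraction. Includes a seeded synthetic
    multi-study generator with phylum-structured correlation blocks and
    planted condition fold effects, so every stage is testable against known
    ground truth.
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
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
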