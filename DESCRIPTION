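Package: coremicro
Title: Delineation of an Interconnected Core Microbiota from Long-Term
    Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to delineate a core microbiota from multi-year monthly
    amplicon time series using association networks. Implements count-table
    preprocessing (rarefaction, prevalence and size-fraction filters,
    seasonally aware imputation, resident-taxon selection), local similarity
    analysis with a mixed theoretical/permutation significance strategy,
    detection and removal of environmentally driven associations via sign
    pattern, interval overlap, interaction information and the data
    processing inequality, core-network construction and characterization
    (density, path length, clustering, cliques, edge-betweenness modularity,
    MCODE modules, hub and connector taxa, random-graph baselines), seasonal
    preference via the indicator value and abundance-weighted environmental
    niche randomization, and a seeded synthetic-community generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    vegan,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
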