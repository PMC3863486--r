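Package: connectofit
Title: Fitting Random-Graph Models to Structural Brain Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds binary structural brain networks from ROI-by-ROI
    fiber-count connectivity matrices and asks which theoretical random-graph
    model describes them best. Implements seven null models (Erdos-Renyi,
    degree-matched Erdos-Renyi, geometric, geometric gene-duplication,
    Barabasi-Albert scale-free, scale-free gene-duplication, and stickiness-
    index models), exact 2-5-node graphlet and automorphism-orbit counting,
    relative graphlet frequency (RGF) distance, graphlet degree distribution
    (GDD) agreement, degree-distribution correlation, path-length and
    clustering difference ratios, small-worldness and global efficiency, and a
    group-level comparison pipeline with tidy outputs. Includes a synthetic
    connectome generator with modular, distance-dependent, heavy-tailed
    fiber-count structure for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
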