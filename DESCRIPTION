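Package: collrisk
Title: Collision Potential and Strike Susceptibility of Birds at Wind Turbines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the collision risk of soaring birds at wind turbine
    structures from carcass-search presence/pseudo-absence data and signed
    distance-to-edge land-use variables (DELVs). Provides a synthetic
    landscape generator with known ground truth, an exact signed Euclidean
    distance-transform engine on a 100 m grid, boosted regression trees with
    stepped cross-validated tree-number selection, model simplification and
    interpretation (relative influence, partial dependence, pairwise
    interactions), and strike-susceptibility mapping that combines the
    predicted collision potential with regional breeding-pair densities,
    including turbine counts per susceptibility zone.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
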