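Package: cultphy
Title: Phylogenetic Comparative Analysis of Discrete Cultural Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cultural phylogenetics with binary traits: matrix
    representation with parsimony (MRP) supertree construction with an
    up-weighted linguistic scaffold, minimum-node-age time calibration and
    ultrametricization, Fitch parsimony ancestral state reconstruction with
    consistency and retention indices, maximum-likelihood ancestral state
    reconstruction under one- and two-parameter Mk models with a likelihood
    decision threshold, and Pagel's (1994) test for correlated evolution of
    two binary characters with a Monte Carlo likelihood-ratio null. Includes
    calibrated simulators for ultrametric trees and discrete characters, and
    a synthetic example dataset of religiosity traits in 33 hunter-gatherer
    societies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape (>= 5.0),
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    phangorn,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
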