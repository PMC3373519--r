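Package: morphoclade
Title: Elastic Shape Analysis, Morphological Parsimony and
    Dispersal-Vicariance Reconstruction for Paleontological Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for the quantitative stages of a
    hadrosaurid systematics study: elastic comparison of 2D anatomical
    outline curves via square-root velocity functions with geodesic
    distances on the pre-shape sphere and non-metric multidimensional
    scaling of the resulting dissimilarities; equally weighted Fitch
    parsimony on discrete morphological matrices with heuristic
    random-addition/branch-swapping search, consistency and retention
    indices, bootstrap proportions and Bremer decay indices; exact
    event-cost dispersal-vicariance reconstruction of ancestral
    geographic ranges on a rooted tree; and length-length allometric
    regressions for body-size estimation. Includes seeded synthetic-data
    generators so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
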