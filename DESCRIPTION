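Package: handregard
Title: Closed-Loop Simulation of Infant Hand Regard and Hand Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the developmental emergence of hand regard, the infant
    behaviour of sustained looking at one's own hand. A three-layer recurrent
    logistic network receives visual input, proprioceptive input and corollary
    discharge from a discrete two-dimensional grid world, decodes its output
    units into hand movements by a simplified population-vector rule, and is
    trained online with a real-time recurrent learning (RTRL) trainer driven
    by feedback-error teaching signals derived from proprioceptively perceived
    hand position. Provides the closed-loop trainer as a model-fitting
    function returning a classed object, test-phase probes of hand-vs-object
    discrimination, and post-hoc analyses of cell assemblies in the recurrent
    weight matrix, U-shaped developmental trajectories and general-movement
    style trajectory metrics.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
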