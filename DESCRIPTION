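Package: mplexr
Title: Reconstruction of Multiplex Networks from Aggregate Topology and
    Partial Observations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the hidden layer structure of a multiplex
    network from its OR-aggregated monoplex topology together with a set of
    partially observed layer memberships. Implements an
    expectation-maximization estimator for a configuration-model likelihood
    that yields per-link posterior reliabilities, an exact enumeration oracle
    for small instances, an information-entropy discrimination indicator that
    predicts reconstruction accuracy from the layers' degree ratio, edge
    overlap and observation fraction, a budget-allocation analysis for
    splitting a limited observation budget between layers, synthetic two-layer
    generators with prescribed characteristics, standard link-prediction
    evaluation metrics, and three validation dynamics (interdependent
    percolation, multiplex random walks, and susceptible-infected spreading on
    temporal networks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    pROC,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
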