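Package: gcda
Title: Graph-Constrained Discriminant Analysis for Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Binary classification of high-dimensional expression data with
    covariance estimates shrunk toward a Gaussian-graphical-model target
    built from the Laplacian of a gene network. Provides linear (one shared
    graph) and quadratic (one graph per class) discriminant analysis, a
    high-dimensional two-sample test of covariance equality to choose
    between the two forms, an Erdos-Renyi simulator of graph-structured
    Gaussian two-class data, Monte Carlo cross-validation with nested
    10-fold hyperparameter selection, and a graph-misspecification
    robustness experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
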