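Package: symnet
Title: Symptom Network Analysis with Regularized Partial Correlations and
    Bayesian Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Two complementary network models for ordinal symptom data such
    as PTSD checklists. The undirected branch estimates a Gaussian graphical
    model from polychoric correlations via the graphical lasso with extended
    BIC tuning, and quantifies node centrality (strength, closeness,
    betweenness) together with bootstrap edge-weight intervals, a
    case-dropping centrality-stability (CS) coefficient, and
    restricted-variance diagnostics. The directed branch learns a Bayesian
    network by BIC hill-climbing with random restarts, averages bootstrap
    replicates with a statistically driven edge-retention threshold and a
    majority direction rule, and annotates edges with BIC importance. A
    synthetic-data module generates ordinal datasets from known latent
    Gaussian graphical models or linear-Gaussian DAGs so that every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
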