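Package: asthmamap
Title: Small-Area Spatial Epidemiology of Childhood Asthma Prevalence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for small-area disease mapping of childhood asthma
    prevalence from census-style area tables: queen-contiguity spatial
    weights, global and local Moran statistics with Monte-Carlo pseudo
    p-values, LISA hotspot classification and cluster-by-covariate
    cross-tabulation, and Bayesian conditional-autoregressive (CAR)
    Poisson regression with Leroux and localised-cluster priors fitted
    by Markov chain Monte Carlo, together with a synthetic area-table
    generator with known ground truth for validation and a seeded
    end-to-end analysis pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    lme4,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
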