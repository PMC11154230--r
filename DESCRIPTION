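Package: fluxmodes
Title: Discretization of Reaction Fluxes into Modes of Signal Execution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse how parameter uncertainty shapes signal execution
    in mass-action reaction-network ODE models. At each simulation time point
    the production fluxes into a target species are compared on a log10 scale;
    reactions within rho orders of magnitude of the largest flux are retained
    as dominant and traced back through the network to a dominant subnetwork.
    The per-time-point subnetwork labels form a dynamic fingerprint for each
    parameter vector; fingerprints are compared with the longest-common-
    subsequence distance and clustered (agglomerative, spectral, or HDBSCAN)
    into probabilistic execution modes. Downstream analyses cover in-silico
    knockdowns, time-of-death and reaction-peak statistics, Bayesian updating
    of mode probabilities after a parameter measurement, and gradient-boosted
    classification of parameter vectors into modes. Includes an abridged
    extrinsic apoptosis reaction model (aEARM) and a synthetic ensemble
    generator with planted dominance regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    Rcpp,
    cluster,
    jsonlite,
    stats,
    utils,
    tools,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    xml2,
    rhdf5,
    optparse
Config/testthat/edition: 3
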