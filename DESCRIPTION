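Package: repgame
Title: Reputation-Biased Spatial Evolutionary Games
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte Carlo simulation of spatial evolutionary games in which
    each player's reputation coevolves with its strategy and biases the
    strategy-adoption (Fermi) rule of its neighbours. Implements the weak
    prisoner's dilemma and the snowdrift game on periodic square lattices
    (von Neumann and Moore neighbourhoods) and Erdos-Renyi random graphs,
    with synchronous updating, a compiled simulation engine, observables
    (cooperation fraction, strategy-retention rates) and extinction-threshold
    estimation by parameter sweeps.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    ggplot2,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
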