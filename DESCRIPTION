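Package: spatialsir
Title: Epidemic Spreading and Control Strategies on Spatial Modular Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Discrete-time SIR epidemics on two-dimensional spatial modular
    networks: a periodic lattice of Erdos-Renyi-wired communities ("cities")
    sparsely linked to their four lattice neighbours. Provides the network
    generator, a compiled synchronous SIR simulator with scheduled
    interventions (social distancing, intra- and inter-community quarantines,
    temporal quarantine windows), closed-form two-threshold theory (local and
    country-wide epidemic thresholds, outbreak size at threshold, critical
    intra-degree and inter-degree inversions), square-lattice bond-percolation
    machinery with an exhaustive SIR-percolation equivalence oracle,
    beta-sweep and spatial-propagation analyses (two-threshold detection,
    circle timescales, shortest-path exponent fits), and control-strategy
    optimization in the (K, Q) structural parameter space.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
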