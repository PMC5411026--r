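Package: colicinsim
Title: Stochastic Lattice Simulation of Colicin-Mediated Bacterial Competition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based lattice model of range-expansion competition between a
    heterogeneously colicin-producing Escherichia coli strain and a sensitive
    (or resistant) competitor. Reproducing cells stochastically switch into a
    toxin-producing state, lyse, and deposit an exponential colicin profile
    that growth-arrests sensitive neighbours; the expanding colony is
    repeatedly coarse-grained so that millimetre-scale colonies remain
    tractable on a 250 x 250 lattice. The package also provides the
    accompanying analysis pipeline: inoculum generators emulating acoustic
    droplet spotting, per-run colony metrics (outcome classification,
    edge-cluster counts, spatial initial-condition measures, transition times,
    expansion rates), growth-rate fitting, and type-I sequential ANOVA with
    eta-squared effect sizes for the linear models linking initial conditions
    to competition outcome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
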