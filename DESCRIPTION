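Package: neurocult
Title: Percolation, Mean-Field and Multi-Agent Dynamics of Developing
    Neuronal Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the development of spontaneous activity in dissociated
    neuronal cultures at three levels of description: continuum percolation of
    neurite-mediated connectivity (overlapping dendrite disks, undirected
    axon-dendrite dipoles, and directed axon-to-dendrite coupling), a
    two-variable activity-energy mean-field map with analytic critical
    connectivities, fixed-point solvers and stability classification, and an
    energy-gated stochastic spiking network with firing-avalanche detection
    and power-law exponent estimation.  Also provides the array-wide spike
    detection rate (ASDR) and burstiness index (BI) metrics, parametric
    regime portraits, and a hypoxia/reoxygenation protocol driver.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
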