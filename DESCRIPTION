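Package: hybridesn
Title: Hybrid-Topology Echo State Networks with Digital and Analog
    Hardware Emulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation of echo state networks (ESNs) whose reservoir is a
    one-way ring augmented with a single linear center (hub) neuron, across
    three abstraction levels: ideal floating point, fixed-point digital
    emulation with a piecewise-linear tanh datapath, and analog device
    emulation in which reservoir weights arise from subthreshold transistor
    threshold-voltage mismatch and the readout is a memristor crossbar.
    Includes normal-equation readout training, threshold and winner-take-all
    classification protocols, reservoir-quality metrics (kernel rank and a
    nearest-neighbour Lyapunov exponent), area and power cost models for the
    analog realization, and seeded generators of EEG-like and EMG-like
    labelled biosignals for end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
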