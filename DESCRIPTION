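Package: microswitch
Title: Inhibitory Switch Dynamics in a Two-Layer Cortical Microcircuit Rate Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Firing-rate (Wilson-Cowan) model of an eight-population mouse
    primary visual cortex microcircuit spanning superficial (L2/3) and deep
    (L5) layers, with pyramidal (PYR) cells and three interneuron classes
    (PV, SST, VIP) per layer. Builds signed effective connectivity matrices
    from pairwise connection-probability and PSP-amplitude tables, scales
    them by a global coupling parameter G, and applies surgical manipulations
    (cell silencing, connection removal, self-connection swaps, weight
    jitter). Integrates the stochastic rate dynamics with a fast compiled
    Euler scheme, characterises layer-wise LFP-proxy spectra with a
    multitaper estimator, and quantifies ultrasensitive and bistable
    switching between SST-dominated and PV/VIP-dominated circuit states via
    Hill-function fits and hysteresis areas of warm-started input sweeps.
    A battery of registered in-silico experiments (coupling sweeps, lesion
    batteries, cell-type stimulation, translaminar state propagation,
    feedforward/feedback drive, inverted self-connectivity) produces tidy
    result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    minpack.lm,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
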