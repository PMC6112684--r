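Package: calstdp
Title: Multi-Pathway Calcium-Based Models of Spike-Timing-Dependent Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for calcium-based models of spike-timing-dependent
    plasticity (STDP) in which several independent signaling pathways (for
    example endocannabinoid and NMDA-receptor dependent mechanisms) compete or
    cooperate at a single synapse, and in which potentiation and depression
    mechanisms inactivate once the cumulative calcium load crosses a
    pathway-specific level.  Each pathway's efficacy follows a bistable
    stochastic differential equation gated by closed-form calcium transients;
    ensembles of synapses are integrated with an Euler-Maruyama scheme, and a
    piecewise Ornstein-Uhlenbeck mean-field solution gives matching switch
    probabilities in closed form at low pairing frequency.  Ships parameter
    presets for cortico-striatal anti-Hebbian STDP, symmetric anti-Hebbian LTD
    scenarios and classical Hebbian STDP, deterministic pair/triplet/frequency
    protocol generators, a sigmoid readout mapping ensemble switch fractions to
    the macroscopic change in synaptic strength, experiment drivers for
    pairing-number heatmaps, pathway blockade, frequency sweeps and triplet
    maps, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
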