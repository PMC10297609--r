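Package: gluspill
Title: Stochastic Simulation of Glutamate Spillover and Extrasynaptic
    NMDA Receptor Activation in Probabilistic Neuropil
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte Carlo simulator of synaptic glutamate release, Brownian
    diffusion among randomly generated overlapping spheroids (neuronal and
    astroglial elements of brain neuropil), stochastic binding to and
    unbinding from astroglial glutamate transporters, and activation of
    extrasynaptic NMDA receptors driven by the simulated free-glutamate
    concentration. Each run regenerates the porous synaptic environment
    anew, so averaged readouts retain the effect of rare transporter-free
    diffusion escape routes. Includes concentric-shell concentration
    profiling with Monte Carlo extracellular-volume estimation, calibration
    of the transporter binding time constant against a reference spatial
    profile, a five-state NMDA receptor kinetic model integrated with
    deSolve, and a reproducible experiment orchestrator with paired
    unbinding-on/off conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
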