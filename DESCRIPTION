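Package: spikebox
Title: Coordinated Spike-Coding Networks and the Error Bounding Box
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of spiking neural networks that use
    coordinated spike coding: leaky integrate-and-fire neurons whose recurrent
    connectivity confines the error of a linear readout to a convex polytope
    (the error bounding box) in signal space. Provides decoder-set and
    bounding-box geometry tools (cross-sections, neighbor angles, Gabor
    decoders), input-signal generators, an event-resolved simulator with
    refractoriness, voltage noise, synaptic delays and slow recurrent dynamics,
    readout bias corrections, a full family of structural and dynamical
    perturbations, coding-error and spike-statistics metrics, and a paired-trial
    benchmarking protocol with an iterative procedure for tuning networks away
    from the runaway "ping-pong" firing regime.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
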