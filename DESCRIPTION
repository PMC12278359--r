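Package: hybridloop
Title: Simulation and Analysis of Hybrid Biological-Artificial Spiking
    Networks Coupled by Closed-Loop Microstimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to simulate and analyse closed-loop brain-computer
    interfaces in which cortical single neurons (SNs) are bidirectionally
    coupled to a small artificial network of integrate-and-fire units
    (IFUs). Spontaneous SN activity is modelled by a first-order Markov
    chain on interspike intervals; responses to intracortical
    microstimulation are modelled by an empirical stimulation-response
    library (evoked-spike probability as a function of time since the
    previous spike, evoked latency distribution, and rebound-spike
    distribution capturing post-stimulus inhibition). The package provides
    the tick-based IFU network simulator with difference-of-exponentials
    synaptic kernels, a closed-loop engine with stimulation-artifact
    obstruction and staggering, feedback-loop detection from elementary
    spike patterns, spike-train correlogram analysis, and parameter sweeps
    over inhibition strength, stimulation delay, and network size with the
    accompanying regression analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
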