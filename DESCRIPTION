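Package: compinhib
Title: Learning Compartment-Specific Feedback Inhibition in Spiking Cortical Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates recurrent spiking networks of two-compartment pyramidal
    cells (soma plus nonlinear apical dendrite) and leaky integrate-and-fire
    interneurons, and optimizes the interneuron connectivity and the
    Tsodyks-Markram short-term plasticity of the pyramidal-to-interneuron
    synapses so that feedback inhibition tracks the excitatory input of each
    compartment separately. Training uses backpropagation through time with
    surrogate spike derivatives and Adam. Includes the accompanying analysis
    suite (paired-pulse ratios, burst/event demultiplexing of spike trains,
    Gaussian-mixture clustering of interneurons into PV-like and SST-like
    classes, specialization and excitation-inhibition balance metrics,
    connection knockouts) and a linear PV/SST/PC rate model for the algebraic
    conditions under which compartment-specific inhibition is possible.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mclust,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
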