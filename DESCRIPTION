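Package: gnwsim
Title: Multilevel Spiking Network Simulation of a Global Neuronal Workspace
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a multilevel spiking neural network spanning a visual-cortex
    local network trained by spike-timing-dependent plasticity (STDP), a global
    neuronal workspace of excitatory and inhibitory leaky integrate-and-fire
    neurons, and a dopamine-driven reinforcement pathway. Provides a Gabor-filter
    visual front-end with latency spike coding, three plasticity rules (classical,
    symmetric GABAergic, and dopamine-modulated STDP with eligibility traces),
    protocols for digit recognition, delay conditioning and trace conditioning,
    synaptic-epigenesis analysis (percentile trajectories, selected/eliminated
    partitions, two-stage growth statistics), and parameter sweeps over spontaneous
    activity rate and excitatory/inhibitory balance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
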