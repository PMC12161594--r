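Package: sleepsyn
Title: Calcium-Based Synaptic Plasticity Across Simulated Sleep-Wake Cycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation framework for synaptic dynamics across the sleep-wake
    cycle. Implements a two-threshold calcium-based model of the bistable
    synaptic efficacy variable driven by NMDAR- and VGCC-sourced calcium,
    an analytic spike-timing-dependent plasticity (STDP) curve with a
    parameter search that classifies rules into Hebbian, STDP, Anti-Hebbian
    and Anti-STDP families, lognormal generators for sleep-like (Up/Down
    alternating) and wake-like (tonic) spike trains with rate matching,
    fixed-firing-pattern efficacy experiments, a Hodgkin-Huxley-based
    cortical network with slow-wave-oscillation parameter search and
    bifurcation analysis, a two-state kinase (CaMKII-like) sleep-wake
    oscillator with Process S, and Bayesian/frequentist comparisons of
    synaptic efficacy between states.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
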