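Package: bgdbs
Title: Basal Ganglia Network Simulation and Energy-Efficient Deep Brain
    Stimulation Waveform Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based simulation of a four-population basal ganglia
    network (thalamus, subthalamic nucleus, external and internal globus
    pallidus) in healthy and Parkinsonian regimes, with a parametric family of
    charge-balanced biphasic deep brain stimulation (DBS) waveforms
    (rectangular, half-sine, Gaussian, with or without an interphase delay).
    Provides an Rcpp fixed-step integrator for the Rubin-Terman-family cell
    models, stochastic sensorimotor-cortex drive, spike detection, and the
    evaluation metrics used to compare stimulation waveforms: an energy plus
    miss-penalty cost function, mutual information, Hilbert-phase locking
    value, a correlation-based synchronization level, and normalized energy
    threshold maps over interphase-delay and frequency grids.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
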