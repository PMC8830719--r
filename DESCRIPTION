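Package: eicrit
Title: Excitation-Inhibition Balanced Spiking Networks at Criticality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of conductance-based excitation-inhibition
    balanced spiking neuronal networks around the critical synchronous
    transition. Provides a fast integrate-and-fire network simulator with
    exponential synaptic kinetics and deterministic or Poisson external drive,
    stimulus protocols for trial ensembles (constant steps and event-related
    alpha-function pulses), multilevel statistics of the resulting dynamics
    (local field potential, spectra, spike-train irregularity and correlation,
    trial-to-trial variability via cross-trial variance and Fano factors,
    neuronal-avalanche extraction with doubly truncated power-law maximum
    likelihood fits, scaling relations and shape collapse), and the
    semi-analytical mean-field reduction of the network (equilibria, Hopf
    eigenvalue analysis, and linear-noise-approximation covariances from the
    Lyapunov equation). Synthetic fixtures with known ground truth are included
    so every estimator is testable without network simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
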