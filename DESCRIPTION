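Package: clustnet
Title: Macroscopic Cluster Topology and the Complexity of Spiking-Network
    Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates networks of Izhikevich spiking-neuron groups wired on a
    Watts-Strogatz macroscopic scaffold and self-organized by spike-timing
    dependent plasticity, then analyzes the resulting group activity and
    structure: local averaged potentials, multiscale (sample) entropy,
    amplitude spectra with band peaks, firing rates, and directed weighted
    complex-network metrics (clustering, shortest paths, degree centrality).
    Provides a study orchestrator that sweeps the rewiring probability,
    joins structural and dynamical observables per neuron group, and
    computes their rank correlations, plus surrogate-signal and toy-network
    generators so every analysis stage is testable without simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
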