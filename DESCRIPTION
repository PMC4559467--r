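Package: drivernet
Title: Self-Organizing Balanced Spiking Networks with STDP and Homeostatic
    Plasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clock-driven simulation of balanced-state networks of leaky
    integrate-and-fire neurons with current-based exponential synapses,
    spike-timing-dependent plasticity (STDP) at excitatory-excitatory and
    inhibitory-excitatory connections, and homeostatic regulation of
    synaptic weights (fast normalization or slow synaptic scaling).
    Provides network constructors (Erdos-Renyi, homogeneous in-degree,
    distance-dependent on a torus), experiment protocols (plastic
    transients, burst stimulation of cell groups, reduced two-neuron and
    fan-in setups), spike-train and weight-distribution statistics
    (driver-neuron detection, shuffle surrogates, power-law and log-normal
    tail fits, synchrony-triggered averages), and closed-form mean-field
    results for the stationary inhibitory weight and the average STDP
    drift on an excitatory synapse.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    pracma,
    methods,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
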