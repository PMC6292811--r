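Package: hexnet
Title: Recurrent Hindbrain Network Simulation of Variable Swim Initiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based simulation and analysis of how a brief touch
    stimulus is extended into long, variable excitation of reticulospinal
    neurons in the hatchling Xenopus tadpole. Implements a random recurrent
    excitatory network of two-compartment 'hindbrain extension' neurons
    (hexNs) driven by near-synchronous sensory-pathway (DLC) spikes, with
    AMPA/NMDA synapses subject to discrete synaptic-strength noise, feeding
    electrically coupled hindbrain descending interneurons (hdINs) whose
    accumulation of noisy EPSPs to firing threshold produces long, variable
    delays to the decision to swim. Includes the electrophysiological
    measurement procedures (spike and EPSP detection, latency statistics,
    response averaging and half-fall times) and a synthetic whole-cell
    recording generator with embedded ground truth so every analysis
    operation is testable without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
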