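Package: ringmem
Title: Spiking Ring-Attractor Model and Trajectory Statistics for Spatial
    Orientation Working Memory in Drosophila
Version: 0.1.0
Authors@R:
    person("Ringmem", "Developers", email = "ringmem@example.org",
           role = c("aut", "cre"))
Description: Simulates the ellipsoid-body/protocerebral-bridge (EB-PB)
    head-direction circuit of the fly central complex as a conductance-based
    leaky integrate-and-fire spiking network with two coupled ring circuits: a
    stabilizing C circuit (EIP-PEI) and a shifting P circuit (EIP-PEN), gated
    by three GABAergic ring-neuron populations.  A two-state Markov-chain
    locomotor model drives the circuit through free-walking trial protocols
    (wild type, ring-neuron suppression, photoactivation), and bump metrics
    (presence, position, FWHM, heading deviation, loss fraction) quantify the
    resulting head-direction bump.  Also implements Buridan-arena trajectory
    statistics (movement-direction projection, fixation density, performance
    index, radar pairing, fixation strength and deviation angle, locomotion
    metrics) together with a synthetic free-walking-fly trajectory generator
    with tunable landmark fixation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
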