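Package: memforce
Title: Memristive Crossbar Synapses and FORCE Learning in Recurrent Rate Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates complex pattern learning in recurrent firing-rate networks
    whose synapses are differential pairs of bounded, pulse-programmed memristors.
    Provides a behavioural device model (long-term potentiation/depression pulse
    trains, programming threshold, fine differential pulse pairs), a two-memristor
    differential synapse and crossbar with a two-stage processing/modulation
    protocol, leaky tanh rate-network dynamics, online and offline recursive
    least-squares (FORCE) training of internal and readout weights, synthetic
    target-pattern generators (sinusoids, composites, dual patterns under static
    control inputs, multi-joint motor trajectories) and experiment drivers for
    pattern learning, device-variation robustness sweeps and a 62-channel motor
    generation task.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
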