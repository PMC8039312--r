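Package: stlrsim
Title: Simulation of Hebbian and Spatiotemporal Synaptic Learning Rules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-layer feed-forward binary-neuron network simulator for
    comparing two biologically grounded synaptic plasticity rules: the
    classical Hebbian learning rule (output-gated potentiation) and the
    spatiotemporal learning rule (STLR), in which LTP/LTD at each synapse is
    decided by a coincidence coefficient among coactive inputs against two
    thresholds, independently of postsynaptic firing. Includes generators for
    constant-weight binary spatial patterns at exact pairwise Hamming
    distance, same- and different-context temporal sequences, unit-sphere
    weight normalization, weight-distribution histograms with mode detection,
    enhancement/invariance/attenuation subset diagnostics, and an experiment
    driver reproducing the pattern-completion versus pattern-discrimination
    contrast between the two rules.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
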