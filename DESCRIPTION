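Package: connectree
Title: Effective Connectivity Inference from Spike Trains with Cost-Sensitive Decision Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Infers effective connectivity in neural circuits from multi-unit
    spike-train recordings. Spike trains are encoded as categorical tables of
    50 ms intervals preceding target-unit spikes, and cost-sensitive decision
    trees of the C4.5/C5.0 family are trained to predict target firing.
    Combinatory, iterative and recursive group-search procedures over the
    recorded units recover the neurons monosynaptically connected to the
    target. Includes a scaled-down Izhikevich spiking-network simulator with
    spike-timing-dependent plasticity and configurable uncertainty, used to
    validate the procedures against circuits with known ground-truth
    connectivity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    Rcpp,
    data.table,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
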