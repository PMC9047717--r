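Package: bpsr
Title: Sparsity-Regularized Backpropagation for Spiking Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Training and analysis of sparse spiking neural networks built
    from heterogeneous leaky integrate-and-fire (LIF) neurons. Provides
    surrogate-gradient backpropagation through time with an O(T) backward
    recursion for flat and recurrent layers, firing-rate (l2) and synaptic
    (l1) sparsity regularization, weight- and gradient-driven synaptic
    rewiring with distance-gated growth, spike encoders (rate, rank-order
    and level-crossing), post-training fixed-point quantization with
    event-driven energy accounting, and directed triad-motif significance
    profiles for comparing learned topologies against reference networks.
    Models are fit with a single function returning a classed object with
    the usual print, summary, coef, predict, plot, simulate and residuals
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
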