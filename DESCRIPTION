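Package: anvn
Title: Artificial Neurovascular Networks: Energy-Constrained Perceptrons
    Fed by a Trainable Vascular Tree
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates artificial neurovascular networks (ANVN): a
    single-hidden-layer perceptron whose hidden-neuron biases are set by
    energy delivered through a weighted k-ary vascular tree. The tree is
    trained by backpropagating an energy-demand gradient from the hidden
    neurons up to the root, with sibling-wise weight normalization
    enforcing energy conservation. Implements the untrained, sequential
    and simultaneous vascular training regimes, a reservoir variant in
    which the network draws only the energy it needs from a fixed source,
    and the accompanying analysis suite: energy efficiency, energy
    deficit, attractor trajectories of per-capita energy consumption,
    per-level vascular weight drift under transfer learning, and the
    correlation between a neuron's ablation-induced error and its energy
    consumption. Includes a synthetic image-classification data generator
    and an IDX file reader so every experiment runs without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
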