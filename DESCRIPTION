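Package: qfuse
Title: Quantum-Inspired Feature-Map Fusion for Multi-Class Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a quantum-inspired hybrid classifier for multi-class
    medical image classification: features from two frozen backbone networks
    are combined through a Hadamard interaction vector, each branch is embedded
    by a Quantum Feature Map (learned phase projection, cosine/sine trigonometric
    embedding, low-rank multiplicative interaction, and L2 norm scaling), the
    three resulting tokens are fused by multi-head self-attention, and a small
    multilayer perceptron produces class probabilities. Includes channel-wise
    image normalization, stratified train/validation/test splitting, cross-entropy
    training with decoupled weight decay and cosine annealing, macro-F1 early
    stopping, confusion-matrix metrics (per-class and support-weighted aggregates),
    and a synthetic five-class image and feature-vector generator with controllable
    class separability for end-to-end testing without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    nnet,
    withr
Config/testthat/edition: 3
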