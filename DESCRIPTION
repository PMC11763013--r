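Package: pairslice
Title: Neuron-Pair Structural Learning and Time-Sliced Decoding for Spiking Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A clock-driven simulator for layered leaky integrate-and-fire
    (LIF) spiking networks with alpha-shaped post-synaptic currents, plus the
    surrounding pipeline for image classification by spike-pattern memory:
    exponential rank-order latency encoding of 28x28 grayscale images,
    Hebbian neuron-pair formation from co-firing statistics, unsupervised
    STDP-based pair refinement, 2- and 3-layer neuron-group topology
    construction, and time-sliced "expression" decoding with Jaccard-distance
    classification. Includes a synthetic glyph generator, an IDX (MNIST
    format) reader/writer, deletion-noise corruption, and runners for
    slice-count, frequency-threshold, preset-current and noise-robustness
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
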