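#' Construct a network topology
#'
#' A topology bundles named layers, a synapse table and per-layer DC preset
#' currents with the neuron and plasticity parameters needed to simulate it.
#' Neuron ids are 0-based within each layer. The `input` layer (if present)
#' is virtual: its spikes are prescribed by the encoded input pattern rather
#' than integrated.
#'
#' @param layers Named integer vector of layer sizes, e.g.
#'   `c(input = 576, M1 = 576)`.
#' @param synapses Tibble with columns `pre_layer`, `pre_id`, `post_layer`,
#'   `post_id`, `weight` (PSC peak amplitude, pA), `kind` (`"static"` or
#'   `"stdp"`) and `delay_ms`. `NULL` means no synapses.
#' @param lif A [lif_params()] object.
#' @param stdp An [stdp_params()] object (used when simulating with
#'   `plastic = TRUE`).
#' @param preset Named numeric vector of per-layer DC amplitudes in pA;
#'   layers not named receive 0.
#' @return An object of class `snn_topology`.
#' @export
snn_topology <- function(layers, synapses = NULL, lif = lif_params(),
                         stdp = stdp_params(), preset = NULL) {
  stopifnot(!is.null(names(layers)), all(layers >= 1))
  if (is.null(synapses)) {
    synapses <- tibble(
      pre_layer = character(), pre_id = integer(),
      post_layer = character(), post_id = integer(),
      weight = numeric(), kind = character(), delay_ms = numeric()
    )
  }
  bad <- !(synapses$pre_layer %in% names(layers)) |
    !(synapses$post_layer %in% names(layers)) |
    synapses$pre_id < 0 | synapses$pre_id >= layers[synapses$pre_layer] |
    synapses$post_id < 0 | synapses$post_id >= layers[synapses$post_layer]
  if (any(bad)) abort("synapse endpoints reference non-existent neurons")
  pre <- stats::setNames(rep(0, length(layers)), names(layers))
  if (!is.null(preset)) pre[names(preset)] <- preset
  structure(
    list(layers = layers, synapses = synapses, lif = lif, stdp = stdp,
         preset = pre),
    class = "snn_topology"
  )
}

#' @export
print.snn_topology <- function(x, ...) {
  cat("<snn_topology> layers:",
      paste(sprintf("%s(%d)", names(x$layers), x$layers), collapse = ", "),
      "|", nrow(x$synapses), "synapses (",
      sum(x$synapses$kind == "stdp"), "plastic )\n")
  invisible(x)
}

#' Base encoder-to-memory topology
#'
#' Input layer of `n` neurons connected one-to-one to a memory layer `M1` of
#' the same size with static suprathreshold synapses, so `M1` reproduces the
#' encoded input spike timing (plus the synaptic delay).
#'
#' @param lif A [lif_params()] object.
#' @param n Layer size (576 for the standard 4-block 12x12 encoding).
#' @param w_in Static input synapse weight, pA.
#' @param delay_ms Synaptic delay, ms.
#' @param stdp An [stdp_params()] object carried along for later training.
#' @return An `snn_topology`.
#' @export
build_base_topology <- function(lif = lif_params(), n = 576,
                                w_in = default_input_weight(),
                                delay_ms = 1, stdp = stdp_params()) {
  syn <- tibble(
    pre_layer = "input", pre_id = 0:(n - 1L),
    post_layer = "M1", post_id = 0:(n - 1L),
    weight = w_in, kind = "static", delay_ms = delay_ms
  )
  snn_topology(c(input = n, M1 = n), syn, lif = lif, stdp = stdp)
}

#' Attach a constant preset current to a layer
#'
#' All neurons of the layer receive the DC amplitude for the whole
#' simulation. Sub-rheobase amplitudes depolarize ("sub-excite") neurons
#' without making a silent network fire.
#'
#' @param topology An `snn_topology`.
#' @param layer Layer name.
#' @param amplitude DC amplitude, pA.
#' @return The modified topology.
#' @export
attach_preset_current <- function(topology, layer, amplitude) {
  if (!layer %in% names(topology$layers)) {
    abort(sprintf("unknown layer '%s'", layer))
  }
  topology$preset[layer] <- amplitude
  topology
}

#' Grid coordinates of encoder/memory neurons
#'
#' Decodes the block-major neuron id convention
#' `id = block * 144 + row * 12 + col` used by the 4x12x12 encoder layout.
#'
#' @param id Integer neuron ids (0-based).
#' @return A tibble with columns `neuron_id`, `block`, `row`, `col`
#'   (all 0-based).
#' @export
neuron_coords <- function(id) {
  id <- as.integer(id)
  within <- id %% 144L
  tibble(
    neuron_id = id,
    block = id %/% 144L,
    row = within %/% 12L,
    col = within %% 12L
  )
}

#' @exportS3Method generics::tidy
tidy.snn_topology <- function(x, ...) x$synapses
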