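#' Parameters for Hebbian neuron-pair formation
#'
#' @param T_thre Co-firing window in ms: an ordered pair (pre, post) counts a
#'   presentation when `0 < T(post) - T(pre) <= T_thre` for the neurons'
#'   first spikes. The default (10 ms) is half the STDP potentiation time
#'   constant, so counted co-firings are exactly the ones that would drive
#'   substantial potentiation in the refinement step.
#' @param S_thre Neighbourhood radius in grid units (Chebyshev distance on
#'   the 12x12 block grid; pairs never cross feature blocks).
#' @param C_thre Absolute occurrence-count threshold, or `NULL` to derive it
#'   per digit as `ceiling(C_frac * presentations)`.
#' @param C_frac Fraction of a digit's presentations used when `C_thre` is
#'   `NULL`.
#' @return An object of class `pair_params`.
#' @export
pair_params <- function(T_thre = 10, S_thre = 1, C_thre = NULL, C_frac = 0.4) {
  stopifnot(T_thre > 0, S_thre >= 1, is.null(C_thre) || C_thre >= 1,
            C_frac > 0, C_frac <= 1)
  structure(list(T_thre = T_thre, S_thre = as.integer(S_thre),
                 C_thre = C_thre, C_frac = C_frac),
            class = "pair_params")
}

# ordered neighbour pairs on the block-major 4x12x12 id layout
neighbor_pairs <- function(S_thre = 1, n_blocks = 4, grid = 12) {
  coords <- neuron_coords(0:(n_blocks * grid * grid - 1L))
  offs <- expand.grid(dr = -S_thre:S_thre, dc = -S_thre:S_thre)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  out <- map(seq_len(nrow(offs)), function(i) {
    r2 <- coords$row + offs$dr[i]
    c2 <- coords$col + offs$dc[i]
    ok <- r2 >= 0 & r2 < grid & c2 >= 0 & c2 < grid
    tibble(
      pre = coords$neuron_id[ok],
      post = coords$block[ok] * grid * grid + r2[ok] * grid + c2[ok]
    )
  })
  bind_rows(out) |> arrange(.data$pre, .data$post)
}

#' Form candidate neuron pairs from per-digit co-firing statistics
#'
#' Implements the Hebbian "fire together, wire together" step: for each digit
#' and each ordered pair of same-block grid neighbours (Chebyshev distance at
#' most `S_thre`), count the presentations in which the candidate post
#' neuron's first spike follows the pre neuron's first spike by at most
#' `T_thre` ms (strictly later), and keep the pair when the count reaches
#' the occurrence threshold.
#'
#' @param spikes Tibble of memory-layer spikes with columns `digit`,
#'   `sample`, `neuron_id`, `time_ms` (one row per spike; only the first
#'   spike per neuron and presentation is used).
#' @param params A [pair_params()] object.
#' @param digits Digits that must be present; defaults to those observed.
#'   An expected digit with no recorded presentations is an error.
#' @param n_neurons Size of the memory-layer id space.
#' @param grid Side of the square per-block grid.
#' @return A tibble `digit`, `pre`, `post`, `n_cooccur`, `n_samples`.
#' @export
form_pairs <- function(spikes, params = pair_params(), digits = NULL,
                       n_neurons = 576, grid = 12) {
  digits <- digits %||% sort(unique(spikes$digit))
  missing <- setdiff(digits, unique(spikes$digit))
  if (length(missing) > 0) {
    abort(paste("no spike records for digit(s):", paste(missing, collapse = ", ")))
  }
  n_blocks <- n_neurons %/% (grid * grid)
  nb <- neighbor_pairs(params$S_thre, n_blocks, grid)

  first <- spikes |>
    summarise(time_ms = min(.data$time_ms),
              .by = c("digit", "sample", "neuron_id"))

  out <- map(digits, function(d) {
    fd <- first |> filter(.data$digit == d)
    samples <- unique(fd$sample)
    n_pres <- length(samples)
    C <- params$C_thre %||% ceiling(params$C_frac * n_pres)
    # first-spike time matrix: presentations x neurons (NA = silent)
    Tm <- matrix(NA_real_, n_pres, n_neurons)
    Tm[cbind(match(fd$sample, samples), fd$neuron_id + 1L)] <- fd$time_ms
    D <- Tm[, nb$post + 1L, drop = FALSE] - Tm[, nb$pre + 1L, drop = FALSE]
    cnt <- colSums(D > 0 & D <= params$T_thre, na.rm = TRUE)
    keep <- cnt >= C
    tibble(digit = d, pre = nb$pre[keep], post = nb$post[keep],
           n_cooccur = as.integer(cnt[keep]), n_samples = n_pres)
  })
  bind_rows(out)
}

#' Train candidate-pair synapse weights with unsupervised STDP
#'
#' Instantiates plastic synapses for the union of all candidate pairs on top
#' of the base topology, then for each digit in turn: resets every plastic
#' weight to `w_init`, presents that digit's encoded samples sequentially
#' with STDP enabled, and records the final weight of every candidate pair.
#' Labels only group the presentation rounds; they never enter the dynamics.
#'
#' @param candidates Pair candidates from [form_pairs()].
#' @param encodings Tibble with columns `digit`, `sample` and list-column
#'   `pattern` of `spike_pattern` objects (one encoded image each).
#' @param base Base topology from [build_base_topology()].
#' @param w_init Initial plastic weight, pA.
#' @param duration,dt Simulation window and step, ms.
#' @param delay_ms Delay of the pair synapses, ms.
#' @return A tibble `pre`, `post`, `digit`, `weight` covering every
#'   (candidate pair) x (digit) combination.
#' @export
train_pair_weights <- function(candidates, encodings, base,
                               w_init = stdp_params()$w_max / 4,
                               duration = 120, dt = 0.1, delay_ms = 1) {
  if (nrow(candidates) == 0) abort("no candidate pairs to train")
  union_pairs <- candidates |> distinct(.data$pre, .data$post) |>
    arrange(.data$pre, .data$post)
  digits <- sort(unique(encodings$digit))

  plastic_syn <- tibble(
    pre_layer = "M1", pre_id = union_pairs$pre,
    post_layer = "M1", post_id = union_pairs$post,
    weight = w_init, kind = "stdp", delay_ms = delay_ms
  )
  topo <- snn_topology(base$layers, bind_rows(base$synapses, plastic_syn),
                       lif = base$lif, stdp = base$stdp, preset = base$preset)
  n_static <- nrow(base$synapses)
  plastic_rows <- n_static + seq_len(nrow(union_pairs))

  out <- map(digits, function(d) {
    topo$synapses$weight[plastic_rows] <- w_init
    pats <- encodings |> filter(.data$digit == d) |> arrange(.data$sample)
    for (p in pats$pattern) {
      sim <- simulate_network(topo, p, duration = duration, dt = dt,
                              plastic = TRUE, record = character())
      topo$synapses$weight <- sim$weights$weight
    }
    tibble(pre = union_pairs$pre, post = union_pairs$post, digit = d,
           weight = topo$synapses$weight[plastic_rows])
  })
  bind_rows(out)
}

#' Refine candidate pairs by digit dominance and post-neuron uniqueness
#'
#' Rule 1: a pair is assigned to the digit with its largest trained weight,
#' but only if that weight is positive and at least `dominance_ratio` times
#' the second-largest digit weight; otherwise the pair is dropped. Rule 2:
#' among surviving pairs sharing a post neuron, only the largest-weight pair
#' is retained (ties broken towards the lowest pre id).
#'
#' @param weights Pair-by-digit weight table from [train_pair_weights()].
#' @param dominance_ratio Required ratio (> 1) between the best and
#'   second-best digit weight.
#' @return A `refined_pairs` tibble `digit`, `pre`, `post`, `weight` with
#'   unique post neurons; the ratio used is stored as attribute
#'   `dominance_ratio`.
#' @export
refine_pairs <- function(weights, dominance_ratio = 1.2) {
  stopifnot(dominance_ratio > 1)
  ranked <- weights |>
    arrange(.data$pre, .data$post, desc(.data$weight), .data$digit) |>
    summarise(
      digit = first(.data$digit),
      w1 = first(.data$weight),
      w2 = if (n() > 1) nth(.data$weight, 2) else 0,
      .by = c("pre", "post")
    ) |>
    filter(.data$w1 > 0, .data$w1 >= dominance_ratio * .data$w2)

  refined <- ranked |>
    rename(weight = "w1") |>
    arrange(.data$post, desc(.data$weight), .data$pre) |>
    filter(row_number() == 1, .by = "post") |>
    select("digit", "pre", "post", "weight") |>
    arrange(.data$digit, .data$pre, .data$post)
  structure(refined, dominance_ratio = dominance_ratio,
            class = c("refined_pairs", class(tibble())))
}

#' Build the 2- or 3-layer neuron-group topology
#'
#' On top of the one-to-one input-to-M1 base network, a 2-layer build adds
#' one static intra-M1 synapse per refined pair (pre to post; the monitored
#' layer is M1). A 3-layer build instead creates one dedicated M2 neuron per
#' refined pair and connects the pair's pre and post M1 neurons to it (both
#' M1 and M2 are monitored).
#'
#' Learned STDP weights are transferred to the static testing synapses by
#' linear rescaling from `[0, w_max]` into `[0, w_pair_max]`. The default
#' `w_pair_max` (1080 pA) lies just below the ~1154 pA single-spike firing
#' threshold of the default neuron, so a group's M2 neuron acts as a
#' coincidence detector: one arriving spike sub-excites it, while the pair's
#' pre and post spikes arriving within a few milliseconds of each other
#' drive it across threshold. (A suprathreshold transfer would make M2
#' mirror M1 activity and carry no pair information.)
#'
#' @param refined A `refined_pairs` tibble from [refine_pairs()].
#' @param n_layers 2 or 3.
#' @param lif A [lif_params()] object.
#' @param w_in Static input synapse weight, pA.
#' @param w_pair_max Upper end of the static pair-synapse weight range, pA.
#' @param delay_ms Synaptic delay, ms.
#' @param stdp [stdp_params()] carried in the topology.
#' @return An `snn_topology`; for 3 layers, M2 neuron `i - 1` (0-based)
#'   corresponds to row `i` of `refined`.
#' @export
build_topology <- function(refined, n_layers = 2, lif = lif_params(),
                           w_in = default_input_weight(),
                           w_pair_max = 0.6 * stdp_params()$w_max,
                           delay_ms = 1, stdp = stdp_params()) {
  if (!n_layers %in% c(2, 3)) abort("n_layers must be 2 or 3")
  if (nrow(refined) == 0) abort("refined pair set is empty")
  base <- build_base_topology(lif = lif, w_in = w_in, delay_ms = delay_ms,
                              stdp = stdp)
  refined <- refined |> arrange(.data$digit, .data$pre, .data$post)
  w_static <- refined$weight / stdp$w_max * w_pair_max
  if (n_layers == 2) {
    pair_syn <- tibble(
      pre_layer = "M1", pre_id = refined$pre,
      post_layer = "M1", post_id = refined$post,
      weight = w_static, kind = "static", delay_ms = delay_ms
    )
    layers <- base$layers
  } else {
    k <- nrow(refined)
    pair_syn <- tibble(
      pre_layer = "M1",
      pre_id = c(refined$pre, refined$post),
      post_layer = "M2",
      post_id = rep(0:(k - 1L), 2L),
      weight = rep(w_static, 2L),
      kind = "static", delay_ms = delay_ms
    )
    layers <- c(base$layers, M2 = k)
  }
  snn_topology(layers, bind_rows(base$synapses, pair_syn),
               lif = lif, stdp = stdp)
}
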