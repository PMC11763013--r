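# Exact one-step propagator of the linear LIF + alpha-PSC subsystem.
# State per neuron: y1 (filtered input, jumps by w*e/tau_syn per arriving
# spike of weight w), y2 = I_syn (alpha-shaped PSC, pA), V (mV).
#   y1' = -y1/tau_s;  y2' = y1 - y2/tau_s;
#   V'  = -(V - E_L)/tau_m + (y2 + I_dc)/C_m
# Between spikes the system is linear, so the per-step update is exact for
# any dt; only threshold detection is on the time grid.
lif_propagator <- function(lif, h) {
  ts <- lif$tau_syn
  tm <- lif$tau_m
  d1 <- exp(-h / ts)
  eV <- exp(-h / tm)
  c0 <- 1 / tm - 1 / ts
  if (abs(c0) > 1e-12) {
    P32 <- eV * (exp(c0 * h) - 1) / c0 / lif$C_m
    P31 <- eV * (h * exp(c0 * h) / c0 - (exp(c0 * h) - 1) / c0^2) / lif$C_m
  } else {
    P32 <- eV * h / lif$C_m
    P31 <- eV * h^2 / 2 / lif$C_m
  }
  list(d1 = d1, eV = eV, P31 = P31, P32 = P32,
       PDC = tm / lif$C_m * (1 - eV))
}

#' Simulate a spiking network
#'
#' Clock-driven simulation of an [snn_topology()]: input-layer neurons emit
#' exactly the spikes of the encoded `pattern` (times rounded to the `dt`
#' grid); all other neurons follow leaky integrate-and-fire dynamics with
#' alpha-shaped post-synaptic currents, threshold/reset, an absolute
#' refractory clamp, and optional per-layer DC preset currents. The linear
#' subsystem is advanced with its exact exponential propagator each step, so
#' results are dt-refinement stable; threshold crossings are detected at
#' step boundaries.
#'
#' With `plastic = TRUE`, synapses of kind `"stdp"` are updated online with
#' the nearest-neighbour pair rule of [stdp_delta_w()], using somatic spike
#' times. All threshold crossings of a step are processed before any weight
#' update, using the pre-step spike history, so the result does not depend
#' on neuron ordering within a step.
#'
#' The default path is fully deterministic; `seed` is reserved for
#' stochastic extensions and unused otherwise.
#'
#' @param topology An [snn_topology()].
#' @param pattern A `spike_pattern` tibble (input neuron id, time in ms) from
#'   [encode_latencies()], or `NULL` for no input.
#' @param duration Simulation length in ms; defaults to the pattern's
#'   encoding window plus 20 ms of headroom.
#' @param dt Time step, ms; must divide `duration` and not exceed the
#'   smallest synaptic delay.
#' @param plastic Update `"stdp"` synapses online?
#' @param record Character vector of layer names to record (default: all
#'   simulated layers).
#' @param seed Unused on the deterministic path.
#' @return An object of class `snn_sim`: a list with `spikes` (tibble
#'   `layer`, `neuron_id`, `time_ms`), `weights` (the synapse table with
#'   final weights), `duration` and `dt`.
#' @export
simulate_network <- function(topology, pattern = NULL, duration = NULL,
                             dt = 0.1, plastic = FALSE, record = NULL,
                             seed = NULL) {
  lif <- topology$lif
  syn <- topology$synapses
  if (dt <= 0) abort("dt must be positive")
  if (nrow(syn) > 0 && dt > min(syn$delay_ms) + 1e-12) {
    abort("dt must not exceed the smallest synaptic delay")
  }
  if (is.null(duration)) {
    duration <- (if (!is.null(pattern)) attr(pattern, "t_stop") else 100) + 20
  }
  nsteps <- as.integer(round(duration / dt))
  if (abs(nsteps * dt - duration) > 1e-6) abort("dt must divide duration")

  sim_layers <- setdiff(names(topology$layers), "input")
  record <- record %||% sim_layers
  sizes <- topology$layers[sim_layers]
  offsets <- stats::setNames(c(0L, cumsum(sizes))[seq_along(sizes)], sim_layers)
  N <- sum(sizes)
  gidx <- function(layer, id) offsets[layer] + id + 1L

  # per-neuron DC from preset currents
  I_dc <- rep(topology$preset[sim_layers], times = sizes)

  pr <- lif_propagator(lif, dt)
  Jscale <- exp(1) / lif$tau_syn # y1 jump per pA of PSC peak weight
  ref_steps <- as.integer(round(lif$t_ref / dt))

  # --- synapse bookkeeping ---------------------------------------------
  from_input <- syn$pre_layer == "input"
  int_idx <- which(!from_input)
  in_idx <- which(from_input)
  dsteps_all <- as.integer(round(syn$delay_ms / dt))
  L <- max(dsteps_all, 1L) + 1L

  # input arrivals, aggregated per (step, post neuron)
  arr_by_step <- NULL
  if (!is.null(pattern) && nrow(pattern) > 0 && length(in_idx) > 0) {
    ev <- tibble(
      pre_id = syn$pre_id[in_idx],
      post = gidx(syn$post_layer[in_idx], syn$post_id[in_idx]),
      amt = syn$weight[in_idx] * Jscale,
      dsteps = dsteps_all[in_idx]
    ) |>
      inner_join(
        tibble(pre_id = pattern$neuron_id,
               spk_step = as.integer(round(pattern$time_ms / dt))),
        by = "pre_id", relationship = "many-to-many"
      ) |>
      # a spike at step s arrives at time (s + dsteps) * dt, so it first
      # acts on the membrane during step s + dsteps + 1
      mutate(step = .data$spk_step + .data$dsteps + 1L) |>
      filter(.data$step >= 1L, .data$step <= nsteps) |>
      summarise(amt = sum(.data$amt), .by = c("step", "post"))
    if (nrow(ev) > 0) {
      arr_by_step <- split(ev[c("post", "amt")],
                           factor(ev$step, levels = seq_len(nsteps)))
    }
  }

  # internal synapses: adjacency by presynaptic neuron
  w <- syn$weight
  out_list <- in_stdp <- out_stdp <- NULL
  has_internal <- length(int_idx) > 0
  if (has_internal) {
    pre_g <- gidx(syn$pre_layer[int_idx], syn$pre_id[int_idx])
    post_g <- gidx(syn$post_layer[int_idx], syn$post_id[int_idx])
    ds_int <- dsteps_all[int_idx]
    out_list <- vector("list", N)
    sp <- split(seq_along(int_idx), pre_g)
    out_list[as.integer(names(sp))] <- sp
    if (plastic) {
      is_stdp <- syn$kind[int_idx] == "stdp"
      in_stdp <- vector("list", N)
      sp2 <- split(which(is_stdp), post_g[is_stdp])
      in_stdp[as.integer(names(sp2))] <- sp2
      out_stdp <- vector("list", N)
      sp3 <- split(which(is_stdp), pre_g[is_stdp])
      out_stdp[as.integer(names(sp3))] <- sp3
    }
  }
  w_int <- w[int_idx]
  stdp <- topology$stdp

  # --- state ------------------------------------------------------------
  V <- rep(lif$E_L, N)
  y1 <- numeric(N)
  y2 <- numeric(N)
  refr <- integer(N)
  last_spike <- rep(NA_real_, N)
  B <- matrix(0, L, N)
  spk_g <- vector("list", nsteps)
  spk_t <- numeric(nsteps)
  n_rec <- 0L
  PDC_I <- pr$PDC * I_dc

  for (s in seq_len(nsteps)) {
    t <- s * dt
    r <- (s - 1L) %% L + 1L
    inc <- B[r, ]
    B[r, ] <- 0
    if (!is.null(arr_by_step)) {
      a <- arr_by_step[[s]]
      if (!is.null(a) && nrow(a) > 0) inc[a$post] <- inc[a$post] + a$amt
    }
    y1 <- y1 + inc

    Vn <- lif$E_L + (V - lif$E_L) * pr$eV + pr$P31 * y1 + pr$P32 * y2 + PDC_I
    y2 <- pr$d1 * (y2 + dt * y1)
    y1 <- pr$d1 * y1

    clamped <- refr > 0L
    if (any(clamped)) {
      Vn[clamped] <- lif$V_reset
      refr[clamped] <- refr[clamped] - 1L
    }
    spk <- which(!clamped & Vn >= lif$V_th)
    V <- Vn
    if (length(spk) > 0) {
      V[spk] <- lif$V_reset
      refr[spk] <- ref_steps
      n_rec <- n_rec + 1L
      spk_g[[n_rec]] <- spk
      spk_t[n_rec] <- t

      if (plastic && !is.null(in_stdp)) {
        # all updates use the pre-step spike history (order-independent)
        for (g in spk) {
          ii <- in_stdp[[g]]
          if (!is.null(ii)) {
            lp <- last_spike[pre_g[ii]]
            ok <- !is.na(lp)
            if (any(ok)) {
              iio <- ii[ok]
              w_int[iio] <- w_int[iio] + stdp$A_plus *
                exp(-(t - lp[ok]) / stdp$tau_plus) * (stdp$w_max - w_int[iio])
            }
          }
          oo <- out_stdp[[g]]
          if (!is.null(oo)) {
            lp <- last_spike[post_g[oo]]
            ok <- !is.na(lp)
            if (any(ok)) {
              ooo <- oo[ok]
              w_int[ooo] <- w_int[ooo] - stdp$A_minus *
                exp(-(t - lp[ok]) / stdp$tau_minus) * (w_int[ooo] - stdp$w_min)
            }
          }
        }
      }
      if (has_internal) {
        for (g in spk) {
          oo <- out_list[[g]]
          if (!is.null(oo)) {
            # consumed at step s + ds + 1 (arrival time s*dt + delay)
            dr <- (s + ds_int[oo]) %% L + 1L
            tgt <- cbind(dr, post_g[oo])
            B[tgt] <- B[tgt] + w_int[oo] * Jscale
          }
        }
      }
      last_spike[spk] <- t
    }
  }

  # --- assemble record --------------------------------------------------
  if (n_rec > 0) {
    gids <- unlist(spk_g[seq_len(n_rec)], use.names = FALSE)
    times <- rep(spk_t[seq_len(n_rec)], lengths(spk_g[seq_len(n_rec)]))
    layer_of <- rep(sim_layers, times = sizes)
    id_of <- unlist(map(sizes, function(k) 0:(k - 1L)), use.names = FALSE)
    spikes <- tibble(
      layer = layer_of[gids],
      neuron_id = id_of[gids],
      time_ms = times
    ) |>
      filter(.data$layer %in% record) |>
      arrange(.data$time_ms, .data$layer, .data$neuron_id)
  } else {
    spikes <- tibble(layer = character(), neuron_id = integer(),
                     time_ms = numeric())
  }
  weights <- syn
  weights$weight[int_idx] <- w_int
  structure(
    list(spikes = spikes, weights = weights, duration = duration, dt = dt),
    class = "snn_sim"
  )
}

#' @export
print.snn_sim <- function(x, ...) {
  cat("<snn_sim>", nrow(x$spikes), "spikes over", x$duration, "ms (dt =",
      x$dt, "ms)\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.snn_sim <- function(x, ...) x$spikes

#' Minimal spiking DC current of an isolated neuron
#'
#' Searches a regular amplitude grid for the smallest constant current that
#' makes a single isolated neuron fire at least once within `t_max` ms,
#' using the same exact-propagator dynamics as [simulate_network()] (all
#' candidate amplitudes are integrated in one vectorized pass). The analytic
#' threshold is `C_m * (V_th - E_L) / tau_m` (375 pA at defaults): the
#' steady-state depolarization `I * tau_m / C_m` must strictly exceed
#' `V_th - E_L`, so the result is the smallest grid point above it, 376 pA
#' on a 1 pA grid.
#'
#' @param params A [lif_params()] object.
#' @param step_pA Grid spacing in pA.
#' @param t_max Simulation length per amplitude, ms.
#' @param dt Time step, ms.
#' @return The minimal spiking amplitude in pA.
#' @export
rheobase <- function(params = lif_params(), step_pA = 1, t_max = 1000,
                     dt = 0.1) {
  stopifnot(step_pA > 0)
  I_star <- params$C_m * (params$V_th - params$E_L) / params$tau_m
  n_amp <- ceiling(I_star / step_pA) + max(5L, ceiling(0.1 * I_star / step_pA))
  amps <- seq_len(n_amp) * step_pA
  pr <- lif_propagator(params, dt)
  V <- rep(params$E_L, n_amp)
  spiked <- rep(FALSE, n_amp)
  PDC_I <- pr$PDC * amps
  for (s in seq_len(as.integer(round(t_max / dt)))) {
    V <- params$E_L + (V - params$E_L) * pr$eV + PDC_I
    spiked <- spiked | V >= params$V_th
  }
  if (!any(spiked)) return(NA_real_)
  min(amps[spiked])
}
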