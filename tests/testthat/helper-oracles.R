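# Independent reference implementations used to cross-check the package.

# Plain forward-Euler integrator for a small all-to-all-specified LIF
# microcircuit with alpha PSCs. Deliberately naive and independent of the
# package's exact-propagator engine: state is advanced with first-order
# Euler at a very fine step.
euler_lif_reference <- function(n, synapses, input_spikes, lif = lif_params(),
                                duration = 120, h = 0.001, I_dc = 0) {
  # synapses: data.frame(pre, post, weight, delay) with pre/post in 1..n;
  #   pre = 0 means external input drive indexed by input_spikes$target
  # input_spikes: data.frame(target, time) external spike arrivals (already
  #   delayed) injecting weight w via the matching synapse row pre == 0
  V <- rep(lif$E_L, n)
  y1 <- numeric(n)
  y2 <- numeric(n)
  ref_until <- rep(-Inf, n)
  steps <- round(duration / h)
  out <- list()
  spikes_emitted <- data.frame(neuron = integer(), time = numeric())
  pending <- input_spikes # arrival events: target, time, amount
  Js <- exp(1) / lif$tau_syn
  for (s in seq_len(steps)) {
    t <- s * h
    due <- pending$time <= t
    if (any(due)) {
      for (k in which(due)) {
        y1[pending$target[k]] <- y1[pending$target[k]] + pending$amount[k] * Js
      }
      pending <- pending[!due, , drop = FALSE]
    }
    dV <- (-(V - lif$E_L) / lif$tau_m + (y2 + I_dc) / lif$C_m) * h
    dy2 <- (y1 - y2 / lif$tau_syn) * h
    dy1 <- (-y1 / lif$tau_syn) * h
    V <- V + dV
    y2 <- y2 + dy2
    y1 <- y1 + dy1
    in_ref <- t < ref_until
    V[in_ref] <- lif$V_reset
    fired <- which(!in_ref & V >= lif$V_th)
    for (g in fired) {
      spikes_emitted <- rbind(spikes_emitted,
                              data.frame(neuron = g, time = t))
      V[g] <- lif$V_reset
      ref_until[g] <- t + lif$t_ref
      hit <- synapses[synapses$pre == g, , drop = FALSE]
      if (nrow(hit) > 0) {
        pending <- rbind(pending, data.frame(target = hit$post,
                                             time = t + hit$delay,
                                             amount = hit$weight))
      }
    }
  }
  spikes_emitted
}

# Brute-force neuron-pair oracle: nested loops over every ordered pair of
# neurons that appear in the record (silent neurons cannot form pairs) and
# every presentation.
brute_force_pairs <- function(spikes, params, n_neurons = 576, grid = 12) {
  co <- neuron_coords(0:(n_neurons - 1L))
  active <- sort(unique(spikes$neuron_id))
  out <- list()
  for (d in sort(unique(spikes$digit))) {
    sd_ <- spikes[spikes$digit == d, ]
    samples <- unique(sd_$sample)
    C <- if (!is.null(params$C_thre)) params$C_thre else
      ceiling(params$C_frac * length(samples))
    for (i in active) {
      for (j in active) {
        if (i == j) next
        if (co$block[i + 1] != co$block[j + 1]) next
        if (max(abs(co$row[i + 1] - co$row[j + 1]),
                abs(co$col[i + 1] - co$col[j + 1])) > params$S_thre) next
        cnt <- 0L
        for (s in samples) {
          ti <- sd_$time_ms[sd_$sample == s & sd_$neuron_id == i]
          tj <- sd_$time_ms[sd_$sample == s & sd_$neuron_id == j]
          if (length(ti) == 0 || length(tj) == 0) next
          gap <- min(tj) - min(ti)
          if (gap > 0 && gap <= params$T_thre) cnt <- cnt + 1L
        }
        if (cnt >= C) {
          out[[length(out) + 1]] <- data.frame(digit = d, pre = i, post = j,
                                               n_cooccur = cnt)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(digit = integer(), pre = integer(), post = integer(),
                      n_cooccur = integer()))
  }
  do.call(rbind, out)
}

# random sparse spike records over a sub-grid of the first feature block
random_spike_record <- function(n_digits, n_samples, active_ids, p_fire = 0.7,
                                t_max = 30) {
  recs <- list()
  for (d in seq_len(n_digits) - 1L) {
    for (s in seq_len(n_samples)) {
      fire <- active_ids[runif(length(active_ids)) < p_fire]
      if (length(fire) == 0) next
      recs[[length(recs) + 1]] <- data.frame(
        digit = d, sample = s + d * 1000L, neuron_id = fire,
        time_ms = round(runif(length(fire), 0, t_max), 1)
      )
    }
  }
  do.call(rbind, recs)
}

random_slice_maps <- function(n_slices, universe, p = 0.3,
                              duration = 120) {
  sc <- slice_scheme(n_slices, duration)
  maps <- lapply(seq_len(n_slices), function(i) {
    sort(universe[runif(length(universe)) < p])
  })
  structure(list(maps = maps, scheme = sc, layers = "M1"),
            class = "slice_maps")
}
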