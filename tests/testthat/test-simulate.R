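test_that("silence in, silence out; single suprathreshold spike relays once", {
  topo <- build_base_topology()
  sim <- simulate_network(topo, NULL, duration = 120)
  expect_equal(nrow(sim$spikes), 0)

  # one input spike through a suprathreshold one-to-one synapse:
  # exactly one M1 spike shortly after the 1 ms delay, then nothing
  pat <- structure(tibble::tibble(neuron_id = 42L, time_ms = 10),
                   t_start = 0, t_stop = 100, class = class(tibble::tibble()))
  sim1 <- simulate_network(topo, pat, duration = 120)
  expect_equal(nrow(sim1$spikes), 1)
  expect_equal(sim1$spikes$neuron_id, 42L)
  expect_gt(sim1$spikes$time_ms, 11)   # delay + rise to threshold
  expect_lt(sim1$spikes$time_ms, 15)
})

test_that("DC-driven firing matches the closed-form inter-spike interval within 2%", {
  lp <- lif_params()
  topo <- attach_preset_current(snn_topology(c(M1 = 1), lif = lp), "M1", 500)
  sim <- simulate_network(topo, NULL, duration = 1000, dt = 0.1)
  isis <- diff(sim$spikes$time_ms)
  IR <- 500 * lp$tau_m / lp$C_m  # mV
  t_closed <- lp$t_ref + lp$tau_m *
    log((IR - (lp$V_reset - lp$E_L)) / (IR - (lp$V_th - lp$E_L)))
  expect_lt(abs(mean(isis) - t_closed) / t_closed, 0.02)

  # refractoriness: no ISI below t_ref
  expect_true(all(isis >= lp$t_ref))
})

test_that("halving dt moves spike times by at most one coarse step", {
  img <- generate_glyphs(2, 1, seed = 9, jitter_px = 0, noise_sd = 0)$image[[1]]
  pat <- encode_image(img)
  topo <- build_base_topology()
  a <- simulate_network(topo, pat, duration = 120, dt = 0.1)$spikes
  b <- simulate_network(topo, pat, duration = 120, dt = 0.05)$spikes
  m <- merge(a, b, by = c("layer", "neuron_id"))
  expect_equal(nrow(m), nrow(a))
  # input times round to each grid and crossings are detected at step ends,
  # so refinement can move a spike by up to (not beyond) one coarse step
  expect_true(all(abs(m$time_ms.x - m$time_ms.y) <= 0.1 + 1e-9))
})

test_that("engine agrees with a naive fine-step Euler reference on a microcircuit", {
  # 3-neuron chain: external spike -> n1 -> n2 -> n3, mixed weights
  lp <- lif_params()
  syn <- tibble::tibble(
    pre_layer = c("input", "M1", "M1"), pre_id = c(0L, 0L, 1L),
    post_layer = c("M1", "M1", "M1"), post_id = c(0L, 1L, 2L),
    weight = c(1800, 1500, 1300), kind = "static", delay_ms = 1
  )
  topo <- snn_topology(c(input = 1, M1 = 3), syn, lif = lp)
  pat <- structure(tibble::tibble(neuron_id = 0L, time_ms = 5),
                   t_start = 0, t_stop = 30, class = class(tibble::tibble()))
  got <- simulate_network(topo, pat, duration = 60, dt = 0.05)$spikes

  ref <- euler_lif_reference(
    n = 3,
    synapses = data.frame(pre = c(1, 2), post = c(2, 3),
                          weight = c(1500, 1300), delay = 1),
    input_spikes = data.frame(target = 1, time = 6, amount = 1800),
    lif = lp, duration = 60, h = 0.001
  )
  expect_equal(nrow(got), nrow(ref))
  got <- got[order(got$neuron_id), ]
  ref <- ref[order(ref$neuron), ]
  expect_equal(got$neuron_id + 1L, ref$neuron)
  expect_true(all(abs(got$time_ms - ref$time) < 0.1))
})

test_that("rheobase tracks the closed form for varied parameter sets", {
  withr::local_seed(31)
  for (i in 1:5) {
    lp <- lif_params(C_m = runif(1, 100, 400), tau_m = runif(1, 5, 30),
                     E_L = -70, V_th = runif(1, -60, -40))
    grid <- c(1, 2)[(i %% 2) + 1]
    got <- rheobase(lp, step_pA = grid, t_max = 2000)
    closed <- lp$C_m * (lp$V_th - lp$E_L) / lp$tau_m
    expected <- grid * (floor(closed / grid) + 1) # smallest grid point above
    expect_equal(got, expected)
  }
  # doubling C_m doubles the result (within one grid step)
  lp1 <- lif_params()
  expect_lte(abs(rheobase(lif_params(C_m = 500)) - 2 * rheobase(lp1)), 2)
})

test_that("STDP increments follow the soft-bound pair rule and stay bounded", {
  sp <- stdp_params()
  expect_equal(stdp_delta_w(0, 100, sp), 0)
  expect_equal(stdp_delta_w(sp$tau_plus, sp$w_min, sp),
               sp$A_plus * exp(-1) * (sp$w_max - sp$w_min))
  expect_equal(stdp_delta_w(5, sp$w_max, sp), 0)   # saturated potentiation
  expect_equal(stdp_delta_w(-5, sp$w_min, sp), 0)  # saturated depression
  expect_lt(stdp_delta_w(-3, 500, sp), 0)

  # weight trajectory under random pairings never leaves [w_min, w_max]
  withr::local_seed(17)
  w <- 900
  for (i in 1:500) {
    w <- w + stdp_delta_w(runif(1, -50, 50), w, sp)
    expect_gte(w, sp$w_min)
    expect_lte(w, sp$w_max)
  }
})

test_that("online STDP in the simulator matches the rule applied to spike times", {
  # two M1 neurons driven at a fixed lag through suprathreshold inputs;
  # one plastic synapse between them
  lp <- lif_params()
  sp <- stdp_params()
  syn <- tibble::tibble(
    pre_layer = c("input", "input", "M1"), pre_id = c(0L, 1L, 0L),
    post_layer = c("M1", "M1", "M1"), post_id = c(0L, 1L, 1L),
    weight = c(1800, 1800, 450), kind = c("static", "static", "stdp"),
    delay_ms = 1
  )
  topo <- snn_topology(c(input = 2, M1 = 2), syn, lif = lp, stdp = sp)
  pat <- structure(tibble::tibble(neuron_id = c(0L, 1L), time_ms = c(10, 14)),
                   t_start = 0, t_stop = 30, class = class(tibble::tibble()))
  sim <- simulate_network(topo, pat, duration = 60, dt = 0.1, plastic = TRUE)
  t0 <- sim$spikes$time_ms[sim$spikes$neuron_id == 0]
  t1 <- sim$spikes$time_ms[sim$spikes$neuron_id == 1]
  # the 450 pA plastic synapse is subthreshold, so each M1 neuron fires once
  expect_length(t0, 1)
  expect_length(t1, 1)
  expected_w <- 450 + stdp_delta_w(t1 - t0, 450, sp)
  expect_equal(sim$weights$weight[3], expected_w, tolerance = 1e-10)
  expect_gt(expected_w, 450) # pre-before-post potentiates
})

test_that("preset currents depolarize without firing below rheobase", {
  lp <- lif_params()
  topo <- snn_topology(c(M1 = 1), lif = lp)
  # 0 pA is identical to no current
  s0 <- simulate_network(attach_preset_current(topo, "M1", 0), NULL,
                         duration = 500)
  expect_equal(nrow(s0$spikes), 0)
  # 300 pA (sub-rheobase) stays silent over a long window
  s300 <- simulate_network(attach_preset_current(topo, "M1", 300), NULL,
                           duration = 1000)
  expect_equal(nrow(s300$spikes), 0)
  # 375 pA silent, 376 pA fires: the grid rheobase via the full simulator
  s375 <- simulate_network(attach_preset_current(topo, "M1", 375), NULL,
                           duration = 1000)
  s376 <- simulate_network(attach_preset_current(topo, "M1", 376), NULL,
                           duration = 1000)
  expect_equal(nrow(s375$spikes), 0)
  expect_gt(nrow(s376$spikes), 0)
  expect_error(attach_preset_current(topo, "M7", 100), "unknown layer")
})
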