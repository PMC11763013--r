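mk_maps <- function(sets, duration = 120, layers = "M1") {
  structure(list(maps = sets, scheme = slice_scheme(length(sets), duration),
                 layers = layers),
            class = "slice_maps")
}

test_that("time slicing respects the half-open boundary convention", {
  spikes <- tibble::tibble(
    layer = "M1",
    neuron_id = c(1L, 2L, 3L, 4L),
    time_ms = c(5, 30, 65, 110)
  )
  sm <- slice_spikes(spikes, slice_scheme(2, 120), layers = "M1")
  expect_equal(sm$maps[[1]], c(1L, 2L))
  expect_equal(sm$maps[[2]], c(3L, 4L))

  # n = 1 degenerates to the set of all spiking neurons
  sm1 <- slice_spikes(spikes, slice_scheme(1, 120), layers = "M1")
  expect_equal(sm1$maps[[1]], 1:4)

  # a spike exactly on an internal boundary belongs to the later slice
  onb <- tibble::tibble(layer = "M1", neuron_id = 9L, time_ms = 60)
  smb <- slice_spikes(onb, slice_scheme(2, 120), layers = "M1")
  expect_equal(smb$maps[[1]], integer(0))
  expect_equal(smb$maps[[2]], 9L)

  # duration endpoint falls into the last (closed) slice
  one <- tibble::tibble(layer = "M1", neuron_id = 3L, time_ms = 120)
  expect_equal(slice_spikes(one, slice_scheme(4, 120),
                            layers = "M1")$maps[[4]], 3L)

  # multiple spikes of one neuron in a slice collapse to one membership;
  # no (neuron, slice) activation is lost or duplicated across slices
  withr::local_seed(41)
  many <- tibble::tibble(layer = "M1",
                         neuron_id = sample(0:20, 200, replace = TRUE),
                         time_ms = runif(200, 0, 119.9))
  sc <- slice_scheme(6, 120)
  smm <- slice_spikes(many, sc, layers = "M1")
  want <- unique(data.frame(
    slice = pmin(floor(many$time_ms / 20) + 1, 6),
    id = many$neuron_id
  ))
  expect_equal(sum(lengths(smm$maps)), nrow(want))
  for (i in 1:6) {
    expect_equal(smm$maps[[i]], sort(unique(want$id[want$slice == i])))
  }
})

test_that("expression aggregation thresholds per-sample activation frequency", {
  # a neuron active in slice 2 of 3 out of 10 samples
  samples <- lapply(1:10, function(s) {
    mk_maps(list(c(1L, 2L), if (s <= 3) c(5L) else integer(0)))
  })
  e_in <- build_expression(samples, freq_threshold = 0.2, digit = 0)
  e_out <- build_expression(samples, freq_threshold = 0.4, digit = 0)
  expect_true(5L %in% e_in$maps[[2]])
  expect_false(5L %in% e_out$maps[[2]])
  # always-active neurons survive any threshold <= 1
  expect_equal(e_out$maps[[1]], c(1L, 2L))

  # one sample: expression equals that sample's maps for any threshold <= 1
  single <- build_expression(samples[1], freq_threshold = 1, digit = 0)
  expect_equal(single$maps, samples[[1]]$maps)

  # threshold 0 gives the union of all samples' sets
  e0 <- build_expression(samples, freq_threshold = 0, digit = 0)
  expect_equal(e0$maps[[2]], 5L)

  expect_error(build_expression(list(), 0.2), "sample")
})

test_that("threshold monotonicity: higher threshold gives nested expressions", {
  withr::local_seed(59)
  for (rep in 1:20) {
    samples <- lapply(1:8, function(s) {
      mk_maps(lapply(1:3, function(i) sort(sample(0:30, sample(0:12, 1)))))
    })
    th <- sort(runif(2))
    lo <- build_expression(samples, th[1], digit = 0)
    hi <- build_expression(samples, th[2], digit = 0)
    for (i in 1:3) {
      expect_true(all(hi$maps[[i]] %in% lo$maps[[i]]))
    }
  }
})

test_that("Jaccard distance follows the per-slice set algebra", {
  a <- mk_maps(list(c(1L, 2L, 3L), c(7L, 8L)))
  expect_equal(jaccard_distance(a, a), 0)

  disjoint <- mk_maps(list(c(4L, 5L), c(9L)))
  expect_equal(jaccard_distance(a, disjoint), 2)

  # worked mixed case: slice 1 {a,b,c} vs {b,c,d} -> 1 - 2/4; slice 2 equal
  mixed <- mk_maps(list(c(2L, 3L, 4L), c(7L, 8L)))
  expect_equal(jaccard_distance(a, mixed), 0.5)

  # empty/empty contributes 0; one-sided empty contributes 1
  e1 <- mk_maps(list(integer(0), c(1L)))
  e2 <- mk_maps(list(integer(0), integer(0)))
  expect_equal(jaccard_distance(e1, e2), 1)
  expect_equal(jaccard_distance(e2, e2), 0)

  expect_error(jaccard_distance(a, mk_maps(list(1L))), "slices")
})

test_that("Jaccard distance is a symmetric bounded metric, additive over slices", {
  withr::local_seed(83)
  for (rep in 1:40) {
    u <- 0:25
    x <- random_slice_maps(3, u)
    y <- random_slice_maps(3, u)
    z <- random_slice_maps(3, u)
    dxy <- jaccard_distance(x, y)
    expect_equal(dxy, jaccard_distance(y, x))
    expect_gte(dxy, 0)
    expect_lte(dxy, 3)
    # identity of indiscernibles under the empty-empty convention
    expect_equal(jaccard_distance(x, x), 0)
    # triangle inequality (holds per slice, hence for the sum)
    expect_lte(jaccard_distance(x, z),
               jaccard_distance(x, y) + jaccard_distance(y, z) + 1e-12)
    # additivity across concatenated schemes
    xa <- mk_maps(x$maps[1:2]); xb <- mk_maps(x$maps[3])
    ya <- mk_maps(y$maps[1:2]); yb <- mk_maps(y$maps[3])
    expect_equal(jaccard_distance(xa, ya) + jaccard_distance(xb, yb), dxy)
  }
})

test_that("classification returns the minimum-distance class with stable ties", {
  withr::local_seed(97)
  # 10 random expressions over 100 neurons
  exprs <- lapply(0:9, function(d) {
    maps <- lapply(1:4, function(i) sort(sample(0:99, 25)))
    structure(list(digit = d, maps = maps, scheme = slice_scheme(4, 120),
                   layers = "M1", freq_threshold = 0.2, n_samples = 10),
              class = "snn_expression")
  })
  arch <- expression_archive(exprs)

  # a perturbed copy of class 7 (10% membership flips) classifies as 7
  sample7 <- lapply(exprs[[8]]$maps, function(m) {
    flip <- sample(0:99, 10)
    sort(union(setdiff(m, flip), setdiff(flip, m)))
  })
  got <- classify_sample(mk_maps(sample7), arch)
  expect_equal(got$class, 7L)
  expect_length(got$distances, 10)
  # brute-force re-check of the argmin
  d_all <- vapply(exprs, function(e) jaccard_distance(e, mk_maps(sample7)),
                  numeric(1))
  expect_equal(unname(got$distances), d_all)
  expect_equal(got$class, which.min(d_all) - 1L)

  # exact copy of class 3 has distance 0
  got3 <- classify_sample(mk_maps(exprs[[4]]$maps), arch)
  expect_equal(got3$class, 3L)
  expect_equal(min(got3$distances), 0)

  # all-empty sample: distances tie across equally-sized expressions -> class 0
  empty <- mk_maps(lapply(1:4, function(i) integer(0)))
  gote <- classify_sample(empty, arch)
  expect_equal(unname(gote$distances), rep(4, 10))
  expect_equal(gote$class, 0L)
})
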