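#' Experiment configuration
#'
#' Bundles every knob of the end-to-end pipeline: data source, split sizes,
#' encoding and simulation windows, network depth, the slice-count and
#' frequency-threshold grids, the pair-count cap, preset currents and seeds.
#'
#' @param dataset `"synthetic"` (glyph generator) or `"idx"` (MNIST-format
#'   files; set `idx_path`).
#' @param idx_path Directory holding an IDX image/label pair (used when
#'   `dataset = "idx"`).
#' @param classes Number of classes (synthetic data).
#' @param n_train_per_class,n_test_per_class Split sizes per class.
#' @param encoding_ms Encoding window length, ms.
#' @param sim_ms Simulation window, ms; must be at least `encoding_ms + 20`
#'   so delayed spikes are covered.
#' @param n_layers Network depth: 2 or 3.
#' @param slice_counts Integer vector of slice counts to evaluate.
#' @param freq_thresholds Numeric vector of expression frequency thresholds.
#' @param max_pairs Optional cap: keep only the top-`max_pairs` refined pairs
#'   by weight.
#' @param jitter_px,noise_sd Glyph generator settings.
#' @param v_min Encoder sub-threshold cutoff.
#' @param dt Simulation step, ms.
#' @param seed Master seed: drives data generation and any derived
#'   randomness.
#' @param lif,stdp,pairs Parameter objects ([lif_params()], [stdp_params()],
#'   [pair_params()]).
#' @param dominance_ratio Pair-refinement dominance ratio.
#' @param w_init Initial plastic weight for pair training, pA.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(dataset = c("synthetic", "idx"),
                              idx_path = NULL,
                              classes = 10,
                              n_train_per_class = 200,
                              n_test_per_class = 50,
                              encoding_ms = 100,
                              sim_ms = encoding_ms + 20,
                              n_layers = 2,
                              slice_counts = c(2, 3, 4, 6),
                              freq_thresholds = c(0.2, 0.4, 0.5),
                              max_pairs = NULL,
                              jitter_px = 2, noise_sd = 8,
                              v_min = 0.05,
                              dt = 0.1,
                              seed = 1,
                              lif = lif_params(),
                              stdp = stdp_params(),
                              pairs = pair_params(),
                              dominance_ratio = 1.2,
                              w_init = stdp_params()$w_max / 4) {
  dataset <- match.arg(dataset)
  if (sim_ms < encoding_ms + 20) {
    abort("sim_ms must be at least encoding_ms + 20 to cover delayed spikes")
  }
  stopifnot(length(slice_counts) > 0, length(freq_thresholds) > 0,
            n_layers %in% c(2, 3))
  structure(
    list(dataset = dataset, idx_path = idx_path, classes = classes,
         n_train_per_class = n_train_per_class,
         n_test_per_class = n_test_per_class,
         encoding_ms = encoding_ms, sim_ms = sim_ms, n_layers = n_layers,
         slice_counts = slice_counts, freq_thresholds = freq_thresholds,
         max_pairs = max_pairs, jitter_px = jitter_px, noise_sd = noise_sd,
         v_min = v_min, dt = dt, seed = seed, lif = lif, stdp = stdp,
         pairs = pairs, dominance_ratio = dominance_ratio, w_init = w_init),
    class = "experiment_config"
  )
}

load_dataset <- function(config) {
  n_each <- config$n_train_per_class + config$n_test_per_class
  if (config$dataset == "synthetic") {
    all <- generate_glyphs(config$classes, n_each, seed = config$seed,
                           jitter_px = config$jitter_px,
                           noise_sd = config$noise_sd)
  } else {
    all <- read_idx(config$idx_path) |>
      filter(.data$label < config$classes) |>
      mutate(rank = row_number(), .by = "label") |>
      filter(.data$rank <= n_each) |>
      select(-"rank")
  }
  all |>
    mutate(sample = row_number(),
           split = if_else(row_number() <= config$n_train_per_class,
                           "train", "test"),
           .by = "label")
}

encode_set <- function(data, config, bank = default_filter_bank()) {
  data |>
    mutate(pattern = map(.data$image, function(im) {
      encode_image(im, bank, t_start = 0, t_stop = config$encoding_ms,
                   v_min = config$v_min)
    }))
}

simulate_set <- function(encoded, topology, config, plastic = FALSE) {
  encoded |>
    mutate(sim = map(.data$pattern, function(p) {
      simulate_network(topology, p, duration = config$sim_ms,
                       dt = config$dt, plastic = plastic)
    }))
}

spikes_of <- function(simulated, which_layer = "M1") {
  simulated |>
    select(digit = "label", "sample", "sim") |>
    mutate(spikes = map(.data$sim, function(s) {
      s$spikes[s$spikes$layer %in% which_layer, ]
    })) |>
    select(-"sim") |>
    unnest("spikes")
}

monitored_layers <- function(topology) {
  setdiff(names(topology$layers), "input")
}

evaluate_split <- function(test_maps, archives, truth) {
  bind_rows(imap(archives, function(arch, key) {
    preds <- map(test_maps[[arch[[1]]$scheme$n_key]], classify_sample,
                 archive = arch)
    pred_class <- map_int(preds, "class")
    margins <- map_dbl(preds, function(p) {
      d <- sort(p$distances)
      if (length(d) > 1) d[2] - d[1] else NA_real_
    })
    per_class <- tibble(truth = truth, correct = pred_class == truth) |>
      summarise(accuracy = mean(.data$correct), .by = "truth") |>
      arrange(.data$truth)
    tibble(
      n_slices = arch[[1]]$scheme$n,
      freq_threshold = arch[[1]]$freq_threshold,
      accuracy = mean(pred_class == truth),
      mean_margin = mean(margins),
      per_class = list(per_class),
      predictions = list(tibble(truth = truth, predicted = pred_class))
    )
  }))
}

#' Run the full structural-learning + time-slicing pipeline
#'
#' Executes, in order: dataset loading/generation, feature extraction and
#' latency encoding, base-network simulation of the training set, Hebbian
#' pair formation, unsupervised STDP pair training, dominance refinement
#' (with optional top-k cap), 2-/3-layer topology construction, expression
#' building over every configured slice count and frequency threshold, and
#' test-set classification. Everything is deterministic given the config.
#'
#' @param config An [experiment_config()].
#' @param verbose Print stage progress to stderr?
#' @return A `pairslice_run` object: the config plus the trained artifacts
#'   (`pairs`, `pair_weights`, `refined`, `topology`, `archives`) and a
#'   `results` tibble (one row per slice-count x threshold combination with
#'   `accuracy`, `mean_margin` and nested per-class accuracies).
#' @export
run_pipeline <- function(config = experiment_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  say("loading data (%s)", config$dataset)
  data <- load_dataset(config)
  bank <- default_filter_bank()
  say("encoding %d images", nrow(data))
  encoded <- encode_set(data, config, bank)
  train <- encoded |> filter(.data$split == "train")
  test <- encoded |> filter(.data$split == "test")

  say("pair formation: simulating %d training images", nrow(train))
  base <- build_base_topology(lif = config$lif, stdp = config$stdp)
  train_sims <- simulate_set(train, base, config)
  m1_spikes <- spikes_of(train_sims, "M1")
  pairs <- form_pairs(m1_spikes |> select("digit", "sample", "neuron_id", "time_ms"),
                      config$pairs, digits = 0:(config$classes - 1L))
  if (nrow(pairs) == 0) abort("no candidate pairs formed; check pair thresholds")
  say("formed %d candidate pairs", nrow(distinct(pairs, .data$pre, .data$post)))

  say("STDP pair training")
  enc_tbl <- train |> select(digit = "label", "sample", "pattern")
  pair_weights <- train_pair_weights(pairs, enc_tbl, base,
                                     w_init = config$w_init,
                                     duration = config$sim_ms, dt = config$dt)
  refined <- refine_pairs(pair_weights, config$dominance_ratio)
  if (!is.null(config$max_pairs) && nrow(refined) > config$max_pairs) {
    refined <- refined |>
      arrange(desc(.data$weight), .data$pre, .data$post) |>
      head(config$max_pairs) |>
      arrange(.data$digit, .data$pre, .data$post)
  }
  if (nrow(refined) == 0) abort("no pairs survived refinement")
  say("%d refined pairs", nrow(refined))

  topology <- build_topology(refined, n_layers = config$n_layers,
                             lif = config$lif, stdp = config$stdp)
  layers <- monitored_layers(topology)

  say("building expressions (%d training simulations)", nrow(train))
  train_final <- simulate_set(train, topology, config)
  test_final <- simulate_set(test, topology, config)

  schemes <- map(config$slice_counts, slice_scheme, duration = config$sim_ms)
  names(schemes) <- as.character(config$slice_counts)
  slice_all <- function(sims) {
    map(schemes, function(sc) {
      map(sims$sim, slice_spikes, scheme = sc, layers = layers)
    })
  }
  train_maps <- slice_all(train_final)
  test_maps <- slice_all(test_final)

  archives <- list()
  for (nk in names(schemes)) {
    for (th in config$freq_thresholds) {
      exprs <- map(0:(config$classes - 1L), function(d) {
        idx <- which(train_final$label == d)
        build_expression(train_maps[[nk]][idx], th, digit = d)
      })
      arch <- expression_archive(exprs)
      arch[[1]]$scheme$n_key <- nk
      archives[[paste0("n", nk, "_t", th)]] <- arch
    }
  }

  say("classifying %d test images", nrow(test))
  results <- evaluate_split(test_maps, archives, test_final$label) |>
    mutate(n_layers = config$n_layers, .before = 1)

  structure(
    list(config = config, data = data, pairs = pairs,
         pair_weights = pair_weights, refined = refined,
         topology = topology, archives = archives,
         test_encoded = test, test_maps = test_maps,
         results = results),
    class = "pairslice_run"
  )
}

#' @export
print.pairslice_run <- function(x, ...) {
  cat("<pairslice_run>", x$config$classes, "classes,",
      nrow(x$refined), "refined pairs,", x$config$n_layers, "layers\n")
  print(x$results |> select(-"per_class", -"predictions"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pairslice_run <- function(x, ...) {
  x$results |> select(-"per_class", -"predictions")
}

#' @exportS3Method generics::glance
glance.pairslice_run <- function(x, ...) {
  best <- x$results |> arrange(desc(.data$accuracy)) |> head(1)
  tibble(
    classes = x$config$classes,
    n_layers = x$config$n_layers,
    n_candidate_pairs = nrow(distinct(x$pairs, .data$pre, .data$post)),
    n_refined_pairs = nrow(x$refined),
    best_accuracy = best$accuracy,
    best_n_slices = best$n_slices,
    best_freq_threshold = best$freq_threshold
  )
}

#' Classify noise-corrupted test sets at several deletion ratios
#'
#' Applies deletion noise ([corrupt_deletion_noise()]) to the raw test
#' images at each ratio, re-encodes and re-simulates them on the trained
#' topology, and classifies against the run's stored expression archives.
#' Ratio 0 reproduces the clean test set.
#'
#' @param run A `pairslice_run` from [run_pipeline()].
#' @param ratios Deletion ratios in `[0, 1]`.
#' @return A results tibble with one row per ratio x slice count x
#'   threshold.
#' @export
run_noise_experiment <- function(run, ratios = c(0, 0.2, 0.4, 0.6, 0.8, 1)) {
  config <- run$config
  layers <- monitored_layers(run$topology)
  schemes <- map(config$slice_counts, slice_scheme, duration = config$sim_ms)
  names(schemes) <- as.character(config$slice_counts)
  bank <- default_filter_bank()

  bind_rows(imap(ratios, function(ratio, ri) {
    corrupted <- run$test_encoded |>
      mutate(image = imap(.data$image, function(im, i) {
        if (ratio == 0) im else {
          corrupt_deletion_noise(im, ratio, seed = config$seed + 7919L * ri + i)
        }
      }))
    enc <- encode_set(corrupted |> select(-"pattern"), config, bank)
    sims <- simulate_set(enc, run$topology, config)
    test_maps <- map(schemes, function(sc) {
      map(sims$sim, slice_spikes, scheme = sc, layers = layers)
    })
    evaluate_split(test_maps, run$archives, sims$label) |>
      mutate(noise_ratio = ratio, .before = 1)
  }))
}

#' Evaluate preset DC currents on the memory layers
#'
#' For each `(M1, M2)` amplitude pair the trained topology receives the
#' preset currents during the static-synapse phases (expression building and
#' test classification), and accuracy plus the total M2 test-set spike count
#' are reported, together with absolute and relative accuracy deltas against
#' the `(0, 0)` baseline (added automatically when missing). Amplitudes at
#' or above the analytic rheobase trigger a warning (neurons would
#' self-fire) but the run proceeds.
#'
#' @param run A `pairslice_run`; use `n_layers = 3` in its config for M2
#'   currents to be meaningful.
#' @param currents List of length-2 numeric vectors `c(M1_pA, M2_pA)`.
#' @return A results tibble, one row per current pair x slice count x
#'   threshold.
#' @export
run_preset_current_experiment <- function(run,
                                          currents = list(c(0, 0), c(100, 0),
                                                          c(300, 0), c(0, 100),
                                                          c(0, 300))) {
  config <- run$config
  if (!any(map_lgl(currents, function(x) all(x == 0)))) {
    currents <- c(list(c(0, 0)), currents)
  }
  lif <- config$lif
  i_rheo <- lif$C_m * (lif$V_th - lif$E_L) / lif$tau_m
  layers <- monitored_layers(run$topology)
  schemes <- map(config$slice_counts, slice_scheme, duration = config$sim_ms)
  names(schemes) <- as.character(config$slice_counts)

  train_enc <- encode_set(
    run$data |> filter(.data$split == "train") |> select(-any_of("pattern")),
    config)

  out <- map(currents, function(cur) {
    if (any(cur >= i_rheo)) {
      warning(sprintf("preset current %.0f pA is at or above rheobase (%.0f pA); neurons will self-fire",
                      max(cur), ceiling(i_rheo)), call. = FALSE)
    }
    topo <- attach_preset_current(run$topology, "M1", cur[1])
    if ("M2" %in% names(topo$layers)) {
      topo <- attach_preset_current(topo, "M2", cur[2])
    }
    train_sims <- simulate_set(train_enc, topo, config)
    test_sims <- simulate_set(run$test_encoded, topo, config)
    train_maps <- map(schemes, function(sc) {
      map(train_sims$sim, slice_spikes, scheme = sc, layers = layers)
    })
    test_maps <- map(schemes, function(sc) {
      map(test_sims$sim, slice_spikes, scheme = sc, layers = layers)
    })
    archives <- list()
    for (nk in names(schemes)) {
      for (th in config$freq_thresholds) {
        exprs <- map(0:(config$classes - 1L), function(d) {
          idx <- which(train_sims$label == d)
          build_expression(train_maps[[nk]][idx], th, digit = d)
        })
        arch <- expression_archive(exprs)
        arch[[1]]$scheme$n_key <- nk
        archives[[paste0("n", nk, "_t", th)]] <- arch
      }
    }
    m2_spikes <- sum(map_int(test_sims$sim, function(s) {
      sum(s$spikes$layer == "M2")
    }))
    evaluate_split(test_maps, archives, test_sims$label) |>
      mutate(current_M1 = cur[1], current_M2 = cur[2],
             m2_test_spikes = m2_spikes, .before = 1)
  })
  res <- bind_rows(out)
  baseline <- res |>
    filter(.data$current_M1 == 0, .data$current_M2 == 0) |>
    select("n_slices", "freq_threshold", baseline_accuracy = "accuracy")
  res |>
    left_join(baseline, by = c("n_slices", "freq_threshold")) |>
    mutate(
      acc_delta_abs = .data$accuracy - .data$baseline_accuracy,
      acc_delta_rel = if_else(.data$baseline_accuracy > 0,
                              .data$acc_delta_abs / .data$baseline_accuracy,
                              NA_real_)
    )
}

#' Write a result table to CSV
#'
#' Flattens nested list-columns (per-class accuracies, predictions) before
#' writing, so the file round-trips with [utils::read.csv()].
#'
#' @param results A results tibble from [run_pipeline()],
#'   [run_noise_experiment()] or [run_preset_current_experiment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(results, path) {
  flat <- results |> select(-any_of(c("per_class", "predictions")))
  utils::write.csv(flat, path, row.names = FALSE)
  invisible(path)
}
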