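# Monitored neurons from several layers share one integer id space:
# gid = 1000 * layer_index + neuron_id, with layer_index the position of the
# layer in the archive's `layers` vector (0-based). Layer sizes here are
# always < 1000.
NS_STRIDE <- 1000L

encode_gid <- function(layer, neuron_id, layers) {
  (match(layer, layers) - 1L) * NS_STRIDE + as.integer(neuron_id)
}

decode_gid <- function(gid, layers) {
  tibble(
    layer = layers[gid %/% NS_STRIDE + 1L],
    neuron_id = as.integer(gid %% NS_STRIDE)
  )
}

#' Even time-slicing scheme
#'
#' Partitions the simulation window `[0, duration)` into `n` contiguous
#' half-open slices of equal width (the last slice additionally includes the
#' endpoint `duration`).
#'
#' @param n Number of slices (>= 1).
#' @param duration Window length, ms.
#' @return A `slice_scheme`: a list with `n`, `duration` and a `bounds`
#'   tibble (`slice`, `start`, `end`).
#' @export
slice_scheme <- function(n, duration) {
  stopifnot(n >= 1, duration > 0)
  edges <- seq(0, duration, length.out = n + 1)
  structure(
    list(n = as.integer(n), duration = duration,
         bounds = tibble(slice = seq_len(n), start = edges[-(n + 1)],
                         end = edges[-1])),
    class = "slice_scheme"
  )
}

#' Collapse a spike record into per-slice active-neuron sets
#'
#' A neuron belongs to slice `i` iff it spiked at least once within the
#' slice's interval; multiple spikes in one slice collapse to a single
#' membership.
#'
#' @param spikes A spike tibble (`layer`, `neuron_id`, `time_ms`) from
#'   [simulate_network()], or an `snn_sim` object.
#' @param scheme A [slice_scheme()] whose coverage matches the record
#'   duration (checked when the record carries one).
#' @param layers Layer names defining the monitored id namespace, in order.
#' @return A `slice_maps` object: list with `maps` (a list of `n` sorted
#'   integer gid vectors), `scheme` and `layers`.
#' @export
slice_spikes <- function(spikes, scheme, layers = NULL) {
  if (inherits(spikes, "snn_sim")) {
    if (abs(spikes$duration - scheme$duration) > 1e-9) {
      abort("slice scheme does not cover the record duration")
    }
    spikes <- spikes$spikes
  }
  layers <- layers %||% (if (nrow(spikes) > 0) sort(unique(spikes$layer)) else "M1")
  spikes <- spikes[spikes$layer %in% layers, ]
  idx <- pmin(findInterval(spikes$time_ms, scheme$bounds$start), scheme$n)
  gid <- encode_gid(spikes$layer, spikes$neuron_id, layers)
  maps <- map(seq_len(scheme$n), function(i) sort(unique(gid[idx == i])))
  structure(list(maps = maps, scheme = scheme, layers = layers),
            class = "slice_maps")
}

#' @export
print.slice_maps <- function(x, ...) {
  cat("<slice_maps>", x$scheme$n, "slices; set sizes:",
      paste(lengths(x$maps), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.slice_maps <- function(x, ...) {
  bind_rows(imap(x$maps, function(g, i) {
    if (length(g) == 0) return(NULL)
    bind_cols(tibble(slice = i), decode_gid(g, x$layers))
  }))
}

#' Aggregate one digit's samples into its memory expression
#'
#' For every slice, each neuron's activation frequency is the fraction of
#' samples in which it was active within that slice; the expression map of
#' the slice keeps the neurons whose frequency reaches `freq_threshold`
#' (inclusive).
#'
#' @param sample_maps List of `slice_maps` (one per sample, identical
#'   schemes).
#' @param freq_threshold Frequency threshold in `[0, 1]`.
#' @param digit Class id stored with the expression.
#' @return An `snn_expression`: list with `digit`, `maps`, `scheme`,
#'   `layers`, `freq_threshold`, `n_samples`.
#' @export
build_expression <- function(sample_maps, freq_threshold, digit = NA_integer_) {
  if (length(sample_maps) == 0) abort("at least one sample is required")
  stopifnot(freq_threshold >= 0, freq_threshold <= 1)
  n <- sample_maps[[1]]$scheme$n
  n_samples <- length(sample_maps)
  maps <- map(seq_len(n), function(i) {
    counts <- table(unlist(map(sample_maps, function(s) s$maps[[i]]),
                           use.names = FALSE))
    keep <- as.integer(names(counts))[as.numeric(counts) / n_samples >= freq_threshold]
    sort(keep)
  })
  structure(
    list(digit = digit, maps = maps, scheme = sample_maps[[1]]$scheme,
         layers = sample_maps[[1]]$layers,
         freq_threshold = freq_threshold, n_samples = n_samples),
    class = "snn_expression"
  )
}

#' Jaccard distance between two sliced spike patterns
#'
#' Sums the per-slice Jaccard distances `1 - |A n B| / |A u B|` between the
#' corresponding active-neuron sets. A slice where both sets are empty
#' contributes 0 (identical silence is perfect agreement); a slice where
#' exactly one side is empty contributes 1. The result lies in `[0, n]`.
#'
#' @param a,b `slice_maps` or `snn_expression` objects with the same number
#'   of slices.
#' @return A single number in `[0, n]`.
#' @export
jaccard_distance <- function(a, b) {
  ma <- a$maps
  mb <- b$maps
  if (length(ma) != length(mb)) {
    abort("patterns have different numbers of slices")
  }
  sum(map_dbl(seq_along(ma), function(i) {
    u <- length(union(ma[[i]], mb[[i]]))
    if (u == 0) 0 else 1 - length(intersect(ma[[i]], mb[[i]])) / u
  }))
}

#' Collect per-digit expressions into an archive
#'
#' @param expressions List of `snn_expression` objects, one per class.
#' @return An `expression_archive` keyed by digit.
#' @export
expression_archive <- function(expressions) {
  digits <- map_int(expressions, function(e) as.integer(e$digit))
  if (anyNA(digits) || anyDuplicated(digits) > 0) {
    abort("expressions must carry unique digit labels")
  }
  ns <- map_int(expressions, function(e) e$scheme$n)
  if (length(unique(ns)) != 1) abort("expressions use different slice counts")
  names(expressions) <- as.character(digits)
  structure(expressions[order(digits)], class = "expression_archive")
}

#' @export
print.expression_archive <- function(x, ...) {
  cat("<expression_archive>", length(x), "classes,", x[[1]]$scheme$n,
      "slices, freq_threshold =", x[[1]]$freq_threshold, "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.expression_archive <- function(x, ...) {
  bind_rows(map(x, function(e) {
    bind_rows(imap(e$maps, function(g, i) {
      if (length(g) == 0) return(NULL)
      bind_cols(tibble(digit = e$digit, slice = i), decode_gid(g, e$layers))
    }))
  }))
}

#' Classify a sliced sample against an expression archive
#'
#' Computes the Jaccard distance to every class expression and returns the
#' minimum-distance class; ties are broken towards the lowest class id.
#'
#' @param sample A `slice_maps` object.
#' @param archive An [expression_archive()].
#' @return A list with `class` (predicted id) and `distances` (named
#'   numeric vector over all classes).
#' @export
classify_sample <- function(sample, archive) {
  d <- map_dbl(archive, function(e) jaccard_distance(e, sample))
  names(d) <- names(archive)
  list(class = as.integer(names(archive)[which.min(d)]), distances = d)
}

#' Save / load an expression archive as versioned JSON
#'
#' The archive round-trips losslessly: slice bounds, per-class per-slice
#' neuron-id sets (namespaced integers) and aggregation metadata.
#'
#' @param archive An [expression_archive()].
#' @param path Output/input file path.
#' @return `save_expressions()` returns `path` invisibly;
#'   `load_expressions()` returns the archive.
#' @export
save_expressions <- function(archive, path) {
  first <- archive[[1]]
  payload <- list(
    schema = "pairslice-expressions/1",
    n_slices = first$scheme$n,
    duration = first$scheme$duration,
    bounds = unname(map2(first$scheme$bounds$start, first$scheme$bounds$end, c)),
    layers = first$layers,
    freq_threshold = first$freq_threshold,
    n_samples = first$n_samples,
    classes = map(archive, function(e) map(e$maps, as.integer))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_expressions
#' @export
load_expressions <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) abort(paste("not a readable expression archive:", conditionMessage(e)))
  )
  if (!identical(payload$schema, "pairslice-expressions/1")) {
    abort("unsupported or missing expression-archive schema version")
  }
  scheme <- slice_scheme(payload$n_slices, payload$duration)
  layers <- unlist(payload$layers)
  exprs <- imap(payload$classes, function(cls, digit) {
    structure(
      list(digit = as.integer(digit),
           maps = map(cls, function(m) sort(as.integer(unlist(m)))),
           scheme = scheme, layers = layers,
           freq_threshold = payload$freq_threshold,
           n_samples = payload$n_samples),
      class = "snn_expression"
    )
  })
  expression_archive(unname(exprs))
}
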