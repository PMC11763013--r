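#' Oriented stroke-detector filter bank
#'
#' Four fixed 5x5 zero-DC kernels detecting strokes at 0 (horizontal), 45,
#' 90 (vertical) and 135 degrees. Each kernel has a positive ridge three
#' pixels wide along its orientation (matching typical handwritten stroke
#' widths) flanked by negative side lobes, and sums to zero, so constant
#' images produce no response and a stroke at the orthogonal orientation is
#' cancelled exactly.
#'
#' @return An object of class `filter_bank`: a named list of four 5x5
#'   matrices (`deg0`, `deg45`, `deg90`, `deg135`).
#' @export
default_filter_bank <- function() {
  # integer weights by perpendicular distance from the ridge; each kernel
  # sums to zero exactly, and a 1-px line at the orthogonal orientation is
  # cancelled exactly
  a <- row(matrix(0, 5, 5))
  b <- col(matrix(0, 5, 5))
  profile <- function(d, w) {
    k <- matrix(0, 5, 5)
    for (i in seq_along(w)) k[d == i - 1] <- w[i]
    k[d >= length(w)] <- w[length(w)]
    k
  }
  vertical <- profile(abs(b - 3), c(4, 2, -4))     # cols sum 20, 10, -20
  d45 <- profile(abs(a + b - 6), c(4, 2, -3, -3))  # 5,8,12 cells: 20+16-36
  d135 <- profile(abs(a - b), c(4, 2, -3, -3))
  structure(
    list(deg0 = t(vertical), deg45 = d45, deg90 = vertical, deg135 = d135),
    class = "filter_bank"
  )
}

#' Convolve an image with a filter bank and max-pool to feature blocks
#'
#' Applies each 5x5 kernel as a valid (no-padding) cross-correlation
#' (28 -> 24 per axis), rectifies (negative responses clipped to zero),
#' max-pools 2x2 with stride 2 (24 -> 12), and rescales each block by its own
#' maximum into `[0, 1]` (an all-zero block stays all-zero).
#'
#' @param image A 28x28 numeric/integer matrix.
#' @param bank A [default_filter_bank()]-style `filter_bank`.
#' @return A `feature_blocks` object: a named list of four 12x12 matrices
#'   with values in `[0, 1]`.
#' @export
convolve_pool <- function(image, bank = default_filter_bank()) {
  stopifnot(all(dim(image) == c(28L, 28L)))
  image <- matrix(as.numeric(image), 28L, 28L)
  blocks <- map(bank, function(k) {
    conv <- matrix(0, 24L, 24L)
    for (a in 1:5) {
      for (b in 1:5) {
        if (k[a, b] != 0) {
          conv <- conv + k[a, b] * image[a:(a + 23L), b:(b + 23L)]
        }
      }
    }
    conv[conv < 0] <- 0
    odd <- seq(1L, 23L, 2L)
    even <- odd + 1L
    pooled <- pmax(conv[odd, odd], conv[odd, even], conv[even, odd], conv[even, even])
    m <- max(pooled)
    if (m > 0) pooled <- pooled / m
    pooled
  })
  structure(blocks, class = "feature_blocks")
}

#' Encode feature blocks as first-spike latencies (exponential rank-order code)
#'
#' Maps each normalized feature value `v` to a first-spike time
#' `T = t_start + (2 * 0.5^v - 1) * (t_stop - t_start)`: the strongest
#' features (`v = 1`) fire at `t_start`, weaker features fire exponentially
#' later, and values below `v_min` emit no spike. The mapping is strictly
#' decreasing in `v`, so the rank order of spike times is the reverse rank
#' order of feature strength.
#'
#' Input-neuron ids are block-major: `id = block * 144 + row * 12 + col`
#' (0-based, row-major within a block), 576 neurons in total.
#'
#' @param blocks A `feature_blocks` object from [convolve_pool()].
#' @param t_start,t_stop Encoding window bounds in ms (`t_stop > t_start`).
#' @param v_min Sub-threshold cutoff in `(0, 1]`: values below it are silent.
#' @param compat_raw If `TRUE`, use the raw un-rescaled exponential map
#'   `T = (0.5^v - 1) * (t_stop - t_start) + t_start` (times then fall at or
#'   before `t_start`; provided for inspection only).
#' @return A `spike_pattern` tibble with columns `neuron_id` (0-based) and
#'   `time_ms`, and attributes `t_start`, `t_stop`, `n_neurons` (576).
#' @export
encode_latencies <- function(blocks, t_start = 0, t_stop = 100,
                             v_min = 0.05, compat_raw = FALSE) {
  if (t_stop <= t_start) abort("t_stop must be greater than t_start")
  stopifnot(v_min > 0, v_min <= 1)
  v <- unlist(map(blocks, function(b) as.vector(t(b))), use.names = FALSE)
  ids <- 0:(length(v) - 1L)
  fire <- v >= v_min
  tk <- if (compat_raw) {
    (0.5^v[fire] - 1) * (t_stop - t_start) + t_start
  } else {
    t_start + (2 * 0.5^v[fire] - 1) * (t_stop - t_start)
  }
  structure(
    tibble(neuron_id = ids[fire], time_ms = tk),
    t_start = t_start, t_stop = t_stop, n_neurons = length(v),
    class = c("spike_pattern", "tbl_df", "tbl", "data.frame")
  )
}

#' Encode an image end to end
#'
#' Convenience wrapper: [convolve_pool()] then [encode_latencies()].
#'
#' @inheritParams convolve_pool
#' @inheritParams encode_latencies
#' @return A `spike_pattern` tibble; see [encode_latencies()].
#' @export
encode_image <- function(image, bank = default_filter_bank(),
                         t_start = 0, t_stop = 100, v_min = 0.05) {
  encode_latencies(convolve_pool(image, bank), t_start, t_stop, v_min)
}
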