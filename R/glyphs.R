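# Procedural 28x28 stroke templates, one per class. Pixel counts are kept
# between ~40 and ~300 so every rendered glyph has a nonzero fraction in
# [0.05, 0.40], and strokes stay >= 4 px from the border so small jitter
# never clips them.

glyph_templates <- function() {
  blank <- function() matrix(0L, 28L, 28L)
  grid_rc <- expand.grid(r = 1:28, c = 1:28)
  mask_to_img <- function(mask) {
    m <- blank()
    m[cbind(grid_rc$r[mask], grid_rc$c[mask])] <- 255L
    m
  }
  r <- grid_rc$r
  c <- grid_rc$c

  ring <- mask_to_img({
    d <- sqrt((r - 14.5)^2 + (c - 14.5)^2)
    d > 6.8 & d < 9.2
  })
  vbar <- mask_to_img(c >= 13 & c <= 15 & r >= 5 & r <= 24)
  cross <- mask_to_img((c >= 13 & c <= 15 & r >= 5 & r <= 24) |
                         (r >= 13 & r <= 15 & c >= 5 & c <= 24))
  diag_ <- mask_to_img(abs(r - c) <= 1 & r >= 5 & r <= 24 & c >= 5 & c <= 24)
  ell <- mask_to_img((c >= 9 & c <= 11 & r >= 5 & r <= 23) |
                       (r >= 21 & r <= 23 & c >= 9 & c <= 20))
  tee <- mask_to_img((r >= 5 & r <= 7 & c >= 7 & c <= 21) |
                       (c >= 13 & c <= 15 & r >= 5 & r <= 23))
  scurve <- {
    m <- blank()
    for (row in 5:24) {
      mid <- 14 + round(5 * sin((row - 5) / 19 * 2 * pi))
      cols <- pmin(pmax((mid - 1):(mid + 1), 1), 28)
      m[row, cols] <- 255L
    }
    m
  }
  dotgrid <- mask_to_img({
    ctr <- c(8, 14, 20)
    dr <- outer(r, ctr, function(a, b) abs(a - b))
    dc <- outer(c, ctr, function(a, b) abs(a - b))
    near_r <- apply(dr, 1, min)
    near_c <- apply(dc, 1, min)
    near_r + near_c <= 2 & near_r <= 1 & near_c <= 1
  })
  chevron <- {
    m <- blank()
    for (row in 6:20) {
      off <- round((20 - row) * 0.6)
      for (cc in c(14 - off, 15 + off)) {
        m[row, pmin(pmax(cc + 0:1, 1), 28)] <- 255L
      }
    }
    m
  }
  aitch <- mask_to_img((c >= 8 & c <= 9 & r >= 5 & r <= 23) |
                         (c >= 19 & c <= 20 & r >= 5 & r <= 23) |
                         (r >= 13 & r <= 14 & c >= 8 & c <= 20))

  list(ring, vbar, cross, diag_, ell, tee, scurve, dotgrid, chevron, aitch)
}

#' Generate a synthetic labeled glyph dataset
#'
#' Rasterizes a fixed stroke template per class (ring, vertical bar, cross,
#' diagonal, L-shape, T-shape, S-curve, dot grid, chevron, H-shape) onto a
#' 28x28 grid, applies a uniform random integer translation of up to
#' `jitter_px` pixels per axis, and perturbs the stroke pixels with Gaussian
#' intensity noise of standard deviation `noise_sd` (rounded and clipped to
#' `[0, 255]`; the zero background is left untouched so images keep the
#' sparse, zero-background structure of handwritten-digit rasters). The
#' output is a deterministic function of the arguments.
#'
#' @param classes Number of classes, 2--10; class ids are `0:(classes-1)`.
#' @param n_per_class Images per class.
#' @param seed Integer seed.
#' @param jitter_px Maximum absolute translation per axis, in pixels.
#' @param noise_sd Standard deviation of the stroke intensity noise.
#'
#' @return A tibble with list-column `image` (28x28 integer matrices) and
#'   integer column `label`, grouped by class in ascending label order.
#' @export
generate_glyphs <- function(classes = 10, n_per_class, seed,
                            jitter_px = 2, noise_sd = 8) {
  stopifnot(classes >= 2, classes <= 10, n_per_class >= 1,
            jitter_px >= 0, noise_sd >= 0)
  templates <- glyph_templates()[seq_len(classes)]
  local_seed(seed)
  out <- map(seq_len(classes), function(cl) {
    tpl <- templates[[cl]]
    map(seq_len(n_per_class), function(i) {
      img <- tpl
      if (jitter_px > 0) {
        sh <- sample.int(2L * jitter_px + 1L, 2L, replace = TRUE) - jitter_px - 1L
        img <- shift_image(img, sh[1], sh[2])
      }
      if (noise_sd > 0) {
        nz <- img != 0L
        img[nz] <- pmin(pmax(as.integer(round(img[nz] + rnorm(sum(nz), 0, noise_sd))), 0L), 255L)
      }
      img
    })
  })
  tibble(
    image = unlist(out, recursive = FALSE),
    label = rep(0:(classes - 1L), each = n_per_class)
  )
}

# integer translation with zero padding
shift_image <- function(img, dr, dc) {
  out <- matrix(0L, nrow(img), ncol(img))
  src_r <- seq_len(nrow(img)) - dr
  src_c <- seq_len(ncol(img)) - dc
  ok_r <- src_r >= 1 & src_r <= nrow(img)
  ok_c <- src_c >= 1 & src_c <= ncol(img)
  out[ok_r, ok_c] <- img[src_r[ok_r], src_c[ok_c]]
  out
}
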