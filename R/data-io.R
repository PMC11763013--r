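#' Read an IDX image/label archive (MNIST format)
#'
#' Reads the big-endian IDX binary format used by MNIST and MNIST-C: an image
#' file (magic `0x00000803`) holding unsigned-byte 28x28 rasters and a label
#' file (magic `0x00000801`) holding one class id per image.
#'
#' @param images Path to the image IDX file, or a directory containing one
#'   image file and one label file (file names containing `"images"` and
#'   `"labels"` respectively, e.g. `train-images-idx3-ubyte`).
#' @param labels Path to the label IDX file. Ignored when `images` is a
#'   directory.
#' @param n Optional maximum number of images to keep (from the front).
#'
#' @return A tibble with list-column `image` (28x28 integer matrices,
#'   intensities 0--255) and integer column `label`.
#' @seealso [write_idx()], [generate_glyphs()]
#' @export
read_idx <- function(images, labels = NULL, n = NULL) {
  if (dir.exists(images)) {
    files <- list.files(images, full.names = TRUE)
    img_file <- grep("images", files, value = TRUE)
    lab_file <- grep("labels", files, value = TRUE)
    if (length(img_file) != 1 || length(lab_file) != 1) {
      abort("directory must contain exactly one '*images*' and one '*labels*' file")
    }
    images <- img_file
    labels <- lab_file
  }
  if (is.null(labels)) abort("a label file is required alongside the image file")

  con <- file(images, "rb")
  on.exit(close(con), add = TRUE)
  magic <- readBin(con, integer(), 1, size = 4, endian = "big")
  if (!identical(magic, 2051L)) {
    abort(sprintf("bad IDX magic number in image file: %d (expected 2051)", magic))
  }
  dims <- readBin(con, integer(), 3, size = 4, endian = "big")
  n_img <- dims[1]
  if (dims[2] != 28L || dims[3] != 28L) {
    abort(sprintf("expected 28x28 images, file declares %dx%d", dims[2], dims[3]))
  }
  raw_px <- readBin(con, integer(), n_img * 28L * 28L, size = 1, signed = FALSE)
  if (length(raw_px) < n_img * 784L) abort("truncated IDX image file")

  con2 <- file(labels, "rb")
  on.exit(close(con2), add = TRUE)
  magic2 <- readBin(con2, integer(), 1, size = 4, endian = "big")
  if (!identical(magic2, 2049L)) {
    abort(sprintf("bad IDX magic number in label file: %d (expected 2049)", magic2))
  }
  n_lab <- readBin(con2, integer(), 1, size = 4, endian = "big")
  if (n_lab != n_img) {
    abort(sprintf("image/label count mismatch: %d images vs %d labels", n_img, n_lab))
  }
  labs <- readBin(con2, integer(), n_lab, size = 1, signed = FALSE)

  keep <- seq_len(if (is.null(n)) n_img else min(n, n_img))
  imgs <- map(keep, function(i) {
    # IDX stores row-major: fill by row
    matrix(raw_px[((i - 1L) * 784L + 1L):(i * 784L)], 28L, 28L, byrow = TRUE)
  })
  tibble(image = imgs, label = as.integer(labs[keep]))
}

#' Write an image set to IDX files (MNIST format)
#'
#' @param data A tibble with columns `image` (28x28 integer matrices) and
#'   `label`, as produced by [read_idx()] or [generate_glyphs()].
#' @param images,labels Output paths for the image and label files.
#' @return `data`, invisibly.
#' @export
write_idx <- function(data, images, labels) {
  n <- nrow(data)
  con <- file(images, "wb")
  writeBin(c(2051L, n, 28L, 28L), con, size = 4, endian = "big")
  for (m in data$image) {
    writeBin(as.raw(as.integer(t(m))), con)
  }
  close(con)
  con2 <- file(labels, "wb")
  writeBin(c(2049L, n), con2, size = 4, endian = "big")
  writeBin(as.raw(as.integer(data$label)), con2)
  close(con2)
  invisible(data)
}

#' Delete a fraction of the informative pixels of an image
#'
#' Models occlusion/erasure noise: a uniformly chosen subset of the nonzero
#' pixels is set to zero; zero pixels and the surviving nonzero pixels are
#' untouched. Exactly `round(ratio * n_nonzero)` pixels are deleted (base R
#' `round()`, ties to even).
#'
#' @param image A 28x28 integer matrix.
#' @param ratio Fraction of nonzero pixels to delete, in `[0, 1]`.
#' @param seed Integer seed; the corruption is deterministic given the seed.
#' @return The corrupted image matrix.
#' @export
corrupt_deletion_noise <- function(image, ratio, seed) {
  stopifnot(ratio >= 0, ratio <= 1)
  nz <- which(image != 0)
  k <- round(ratio * length(nz))
  if (k > 0) {
    local_seed(seed)
    image[nz[sample.int(length(nz), k)]] <- 0L
  }
  image
}
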