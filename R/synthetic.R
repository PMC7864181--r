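#' Specification of a synthetic brain phantom
#'
#' Describes a piecewise-constant phantom emulating an axial FLAIR-like
#' slice: dark background, a large elliptical "brain", one to three
#' interior tissue blobs, and one small bright "tumor" blob, each with
#' its own mean intensity plus within-class Gaussian noise. Geometry is
#' given in relative coordinates (fractions of height/width) so the same
#' spec scales to any shape.
#'
#' @param shape integer `c(H, W)` (default `c(128, 128)`).
#' @param class_means intensities of background, brain, tissue blobs...,
#'   tumor (pairwise distinct; default `c(10, 90, 140, 220)`).
#' @param class_noise_sd within-class Gaussian standard deviation
#'   (default 4).
#' @param tissue_blobs list of ellipses, each
#'   `c(row, col, r_radius, c_radius)` in relative units, drawn inside
#'   the brain in order (later blobs win on overlap).
#' @param tumor_blob one ellipse, same encoding, for the bright tumor;
#'   its pixel area must be at least 9.
#' @param seed integer seed for the Gaussian noise.
#' @param dtype_max intensity ceiling of the image (default 255).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 128),
                         class_means = c(10, 90, 140, 220),
                         class_noise_sd = 4,
                         tissue_blobs = list(c(0.58, 0.42, 0.16, 0.14)),
                         tumor_blob = c(0.34, 0.64, 0.055, 0.055),
                         seed = 1, dtype_max = 255) {
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 16)) {
    stop("`shape` must be two integers >= 16", call. = FALSE)
  }
  if (anyDuplicated(class_means)) {
    stop("`class_means` must be pairwise distinct", call. = FALSE)
  }
  n_tissue <- length(tissue_blobs)
  if (n_tissue < 1 || n_tissue > 3) {
    stop("need 1 to 3 tissue blobs", call. = FALSE)
  }
  if (length(class_means) != n_tissue + 3) {
    stop("`class_means` must supply background, brain, one mean per ",
         "tissue blob, and tumor", call. = FALSE)
  }
  if (class_noise_sd < 0) stop("`class_noise_sd` must be >= 0", call. = FALSE)
  for (b in c(tissue_blobs, list(tumor_blob))) {
    if (length(b) != 4 || any(b <= 0) || any(b[1:2] >= 1) ||
        b[1] + b[3] > 1 || b[1] - b[3] < 0 ||
        b[2] + b[4] > 1 || b[2] - b[4] < 0) {
      stop("blobs must be c(row, col, r_radius, c_radius) in (0, 1) and ",
           "lie inside the image", call. = FALSE)
    }
  }
  tumor_area <- pi * (tumor_blob[3] * shape[1]) * (tumor_blob[4] * shape[2])
  if (tumor_area < 9) {
    stop("tumor blob area must be at least 9 pixels", call. = FALSE)
  }
  structure(list(shape = shape, class_means = as.numeric(class_means),
                 class_noise_sd = class_noise_sd,
                 tissue_blobs = tissue_blobs, tumor_blob = tumor_blob,
                 seed = as.integer(seed), dtype_max = dtype_max),
            class = "phantom_spec")
}

ellipse_mask <- function(h, w, blob) {
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  cr <- blob[1] * h; cc <- blob[2] * w
  rr <- blob[3] * h; rc <- blob[4] * w
  ((rows - cr) / rr)^2 + ((cols - cc) / rc)^2 <= 1
}

#' Generate a phantom image and its ground-truth label mask
#'
#' Deterministic given `spec$seed`. Classes are painted in draw order
#' (background, brain ellipse, tissue blobs, tumor), so later blobs win
#' on overlap; the returned mask is the exact generating partition.
#' Labels: 1 = background, 2 = brain, 3.. = tissue blobs, and the
#' highest label = tumor.
#'
#' @param spec a [phantom_spec()].
#' @return A list with `image` (a [gray_image()]), `mask` (integer label
#'   matrix) and `tumor_label`.
#' @examples
#' ph <- make_phantom(phantom_spec(shape = c(48, 48), class_noise_sd = 0))
#' table(ph$mask)
#' @export
make_phantom <- function(spec = phantom_spec()) {
  h <- spec$shape[1]; w <- spec$shape[2]
  mask <- matrix(1L, h, w)
  # brain ellipse fills most of the frame
  mask[ellipse_mask(h, w, c(0.5, 0.5, 0.42, 0.38))] <- 2L
  lab <- 2L
  for (b in spec$tissue_blobs) {
    lab <- lab + 1L
    mask[ellipse_mask(h, w, b)] <- lab
  }
  tumor_label <- lab + 1L
  mask[ellipse_mask(h, w, spec$tumor_blob)] <- tumor_label
  img <- matrix(spec$class_means[mask], h, w)
  if (spec$class_noise_sd > 0) {
    img <- with_seed(spec$seed,
                     img + matrix(stats::rnorm(h * w, 0, spec$class_noise_sd),
                                  h, w))
    img <- pmin(pmax(img, 0), spec$dtype_max)
  }
  list(image = gray_image(img, spec$dtype_max), mask = mask,
       tumor_label = tumor_label)
}

#' Add exact-count salt-and-pepper noise
#'
#' Corrupts exactly `round(p * n)` pixels, chosen without replacement
#' under the given seed; each corrupted pixel is set to 0 or the image's
#' `dtype_max` with equal probability. The exact count (rather than
#' per-pixel Bernoulli draws) makes noise-grid experiments reproducible
#' pixel-for-pixel.
#'
#' @param image a [gray_image()] or numeric matrix.
#' @param p fraction of corrupted pixels, in \[0, 0.5\].
#' @param seed integer seed.
#' @return A [gray_image()]; `p = 0` returns the input unchanged.
#' @export
salt_and_pepper <- function(image, p, seed = 1) {
  img <- as_gray_image(image)
  if (length(p) != 1 || is.na(p) || p < 0 || p > 0.5) {
    stop("noise intensity `p` must lie in [0, 0.5]", call. = FALSE)
  }
  if (p == 0) return(img)
  n <- length(img$pixels)
  k <- round(p * n)
  if (k == 0) return(img)
  with_seed(seed, {
    idx <- sample.int(n, k)
    salt <- stats::runif(k) < 0.5
    px <- img$pixels
    px[idx[salt]] <- img$dtype_max
    px[idx[!salt]] <- 0
    gray_image(px, img$dtype_max)
  })
}
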