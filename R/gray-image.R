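#' Grayscale image container
#'
#' A `gray_image` wraps a 2-D numeric matrix of pixel intensities together
#' with the maximum representable value of its storage type (255 for 8-bit
#' data, 65535 for 16-bit). Intensities are kept on their native integer
#' scale (not rescaled to \[0, 1\]) so that cluster centers and similarity
#' scales are reported in the units a user sees in the source file.
#'
#' @param pixels numeric matrix of intensities, all in `[0, dtype_max]`.
#' @param dtype_max maximum representable intensity (default 255).
#' @return An object of class `gray_image` with elements `pixels` and
#'   `dtype_max`.
#' @examples
#' img <- gray_image(matrix(0:255, 16, 16))
#' dim(img$pixels)
#' @export
gray_image <- function(pixels, dtype_max = 255) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a 2-D numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(pixels))) {
    stop("`pixels` contains non-finite values", call. = FALSE)
  }
  if (length(dtype_max) != 1 || dtype_max <= 0) {
    stop("`dtype_max` must be a single positive number", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > dtype_max) {
    stop("pixel values must lie in [0, dtype_max]", call. = FALSE)
  }
  structure(
    list(pixels = pixels, dtype_max = as.numeric(dtype_max)),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d, range [%g, %g], dtype_max = %g\n",
    nrow(x$pixels), ncol(x$pixels), min(x$pixels), max(x$pixels), x$dtype_max
  ))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

# Coerce matrices on the fly so internal code can accept either form.
as_gray_image <- function(x, dtype_max = 255) {
  if (inherits(x, "gray_image")) return(x)
  gray_image(x, dtype_max = dtype_max)
}
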