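#' Guided-filter parameters for the membership transfer model
#'
#' @param radius box-window half-width `r` of the guided filter, in
#'   pixels (integer >= 1). Default 3.
#' @param eps regularizer \eqn{\varepsilon \ge 0} controlling smoothing
#'   strength, on the \[0, 1\] membership scale. Default 0.01.
#' @param subsample integer ratio `s >= 1` of the fast guided filter;
#'   `1` (default) disables the subsampled path.
#' @param median_radius half-width of the median prefilter applied to the
#'   previous iteration's membership maps (default 1, a 3x3 window).
#' @return An object of class `guided_filter_params`.
#' @export
guided_filter_params <- function(radius = 3, eps = 0.01, subsample = 1,
                                 median_radius = 1) {
  radius <- as.integer(radius)
  subsample <- as.integer(subsample)
  median_radius <- as.integer(median_radius)
  if (radius < 1) stop("`radius` must be >= 1", call. = FALSE)
  if (eps < 0) stop("`eps` must be >= 0", call. = FALSE)
  if (subsample < 1) stop("`subsample` must be >= 1", call. = FALSE)
  if (median_radius < 1) stop("`median_radius` must be >= 1", call. = FALSE)
  structure(list(radius = radius, eps = as.numeric(eps),
                 subsample = subsample, median_radius = median_radius),
            class = "guided_filter_params")
}

#' Median filter of a 2-D map
#'
#' Each output value is the median of the (2 `radius` + 1)^2 window around
#' the pixel, with edge-replicated borders. The output range is contained
#' in the input range. Radius 1 uses a vectorized selection network; other
#' radii sort each window.
#'
#' @param map numeric matrix.
#' @param radius window half-width (integer >= 1).
#' @return A matrix of the same shape.
#' @export
median_filter <- function(map, radius = 1) {
  radius <- as.integer(radius)
  if (radius < 1) stop("`radius` must be >= 1", call. = FALSE)
  if (!is.matrix(map)) stop("`map` must be a matrix", call. = FALSE)
  shifts <- window_shifts(map, radius)
  med <- if (radius == 1) {
    median9(shifts)
  } else {
    apply(do.call(cbind, shifts), 1, stats::median)
  }
  matrix(med, nrow(map), ncol(map))
}

#' Guided filter (with optional fast subsampled path)
#'
#' Edge-preserving filter whose output is locally an affine function of
#' the guidance image: within each box window \eqn{k},
#' \deqn{a_k = \frac{\mathrm{mean}(I p) - \mathrm{mean}(I)\,
#'   \mathrm{mean}(p)}{\mathrm{var}(I) + \varepsilon}, \qquad
#'   b_k = \mathrm{mean}(p) - a_k\, \mathrm{mean}(I),}
#' and the output is \eqn{q_i = \bar a_i I_i + \bar b_i} with
#' \eqn{\bar a, \bar b} the window averages of the coefficients. All
#' window means use replicate padding. Windows where
#' \eqn{\mathrm{var}(I) + \varepsilon = 0} (constant guide, no
#' regularization) get \eqn{a_k = 0}.
#'
#' With `params$subsample = s > 1` (the fast guided filter), `p` and `I`
#' are nearest-neighbor downsampled by `s`, the coefficient maps are
#' computed and averaged at low resolution with radius `round(r/s)`, then
#' upsampled before forming the output against the full-resolution guide.
#'
#' @param p filtering input, a numeric matrix.
#' @param guide guidance image `I`, same shape as `p`.
#' @param params a [guided_filter_params()] object.
#' @return A matrix of the same shape as `p`.
#' @export
guided_filter <- function(p, guide, params = guided_filter_params()) {
  if (!is.matrix(p) || !identical(dim(p), dim(guide))) {
    stop("`p` and `guide` must be matrices of identical shape", call. = FALSE)
  }
  s <- params$subsample
  if (s > 1) {
    h <- nrow(p); w <- ncol(p)
    ri <- seq(1, h, by = s); ci <- seq(1, w, by = s)
    r_lo <- max(1L, as.integer(round(params$radius / s)))
    co <- guided_coefficients(p[ri, ci, drop = FALSE],
                              guide[ri, ci, drop = FALSE], r_lo, params$eps)
    # nearest-neighbor upsample of the averaged coefficients
    up_r <- pmin(floor((seq_len(h) - 1) / s) + 1, length(ri))
    up_c <- pmin(floor((seq_len(w) - 1) / s) + 1, length(ci))
    abar <- co$abar[up_r, up_c, drop = FALSE]
    bbar <- co$bbar[up_r, up_c, drop = FALSE]
  } else {
    co <- guided_coefficients(p, guide, params$radius, params$eps)
    abar <- co$abar; bbar <- co$bbar
  }
  abar * guide + bbar
}

guided_coefficients <- function(p, guide, radius, eps) {
  mI <- box_mean(guide, radius)
  mp <- box_mean(p, radius)
  varI <- box_mean(guide * guide, radius) - mI^2
  covIp <- box_mean(guide * p, radius) - mI * mp
  a <- covIp / (varI + eps)
  a[!is.finite(a)] <- 0
  b <- mp - a * mI
  list(abar = box_mean(a, radius), bbar = box_mean(b, radius))
}

#' Membership information transfer between iterations
#'
#' The transfer model couples consecutive iterations of the clustering
#' loop: for each cluster, the previous iteration's membership map is
#' median-filtered to form the guidance matrix, the current map is guided-
#' filtered against it, and the filtered stack is clipped to \[0, 1\] and
#' renormalized per pixel. The median prefilter suppresses impulse noise
#' in the guidance; the guided filter restores edges while smoothing
#' within regions, so membership information flows between adjacent
#' iterations and across each pixel's neighborhood.
#'
#' @param u_pre membership stack of the previous iteration (H x W x c).
#' @param u_cur current membership stack, same shape.
#' @param params a [guided_filter_params()] object.
#' @return The filtered, renormalized membership stack. Pixels whose
#'   clipped cross-cluster sum vanishes (pathological filter output) are
#'   assigned uniform membership `1/c` with a message.
#' @export
transfer_membership <- function(u_pre, u_cur,
                                params = guided_filter_params()) {
  d <- stack_dims(u_cur)
  if (!identical(stack_dims(u_pre), d)) {
    stop("`u_pre` and `u_cur` must share shape", call. = FALSE)
  }
  out <- u_cur
  for (i in seq_len(d[3])) {
    g <- median_filter(u_pre[, , i], params$median_radius)
    out[, , i] <- guided_filter(u_cur[, , i], g, params)
  }
  out[out < 0] <- 0
  out[out > 1] <- 1
  sums <- rowSums(matrix(out, d[1] * d[2], d[3]))
  if (any(sums <= 0)) {
    message(sprintf(
      "transfer_membership: %d pixel(s) with zero filtered membership set to uniform",
      sum(sums <= 0)))
  }
  normalize_stack(out)
}
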