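#' Cluster states: gray centers with spatial centroids
#'
#' A cluster is summarized by its gray-level center \eqn{v_i} and, for the
#' distance-similarity term, a membership-weighted spatial centroid
#' `(row, col)` in pixel units (1-based, matching R matrix indexing).
#'
#' @param gray numeric vector of gray centers, one per cluster.
#' @param row,col numeric vectors of spatial centroids (may be `NA` when
#'   the spatial term is unused).
#' @return A `data.frame` with columns `cluster`, `gray`, `row`, `col`.
#' @export
cluster_states <- function(gray, row = NA_real_, col = NA_real_) {
  data.frame(cluster = seq_along(gray), gray = as.numeric(gray),
             row = as.numeric(row), col = as.numeric(col))
}

#' Adaptive similarity scales from per-cluster dissimilarities
#'
#' For every pixel, the distance scale `D` and gray scale `G` are mean
#' absolute deviations, across clusters, of the pixel's dissimilarities to
#' the cluster centers: `D` from the spatial center distances
#' \eqn{dis(x_k, c_i)} and `G` from the squared gray gaps
#' \eqn{[g(x_k) - g(c_i)]^2}. They adapt the similarity kernels to how
#' spread out a pixel's relations to the clusters are. Scales below
#' `floor` (degenerate pixels whose dissimilarities coincide across all
#' clusters) are floored.
#'
#' Two conventions for `D` are provided (see `scale_mode` in
#' [ifcm_config()]): `"printed"` takes the deviation of the linear
#' distances, `"balanced"` of the squared distances so that the exponent
#' \eqn{dis^2/D} of the distance kernel is scale-free and commensurate
#' with the gray kernel.
#'
#' @param dist array (H x W x c, or n x c) of spatial distances to each
#'   cluster centroid, pixel units.
#' @param gray_gap2 array of the same shape of squared gray gaps to each
#'   cluster center.
#' @param scale_mode `"printed"` (default) or `"balanced"`.
#' @param floor lower bound for both scales (default `1e-12`).
#' @return A list with per-pixel `D` and `G` (shaped like one slice of the
#'   input).
#' @examples
#' d <- array(c(1, 2, 3), c(1, 1, 3))
#' adaptive_scales(d, d^2, scale_mode = "printed")$D  # 2/3
#' @export
adaptive_scales <- function(dist, gray_gap2,
                            scale_mode = c("printed", "balanced"),
                            floor = 1e-12) {
  scale_mode <- match.arg(scale_mode)
  dd <- dim(dist)
  if (is.null(dd) || !identical(dd, dim(gray_gap2))) {
    stop("`dist` and `gray_gap2` must be arrays of identical shape",
         call. = FALSE)
  }
  nc <- dd[length(dd)]
  if (nc < 2) {
    stop("adaptive scales need at least 2 clusters (deviation across a ",
         "single cluster is undefined)", call. = FALSE)
  }
  n <- prod(dd[-length(dd)])
  dm <- matrix(dist, n, nc)
  em <- matrix(gray_gap2, n, nc)
  if (scale_mode == "balanced") dm <- dm^2
  D <- rowMeans(abs(dm - rowMeans(dm)))
  G <- rowMeans(abs(em - rowMeans(em)))
  shape <- if (length(dd) == 3) dd[1:2] else c(n, 1L)
  list(D = array(pmax(D, floor), dim = shape),
       G = array(pmax(G, floor), dim = shape))
}

#' Gray/distance similarity between a pixel and a cluster
#'
#' The similarity is the product of a distance factor and a gray factor,
#' \deqn{Sim(x_k, c_i) = w_d \cdot w_g,}
#' with \eqn{w_d = \exp(-dis^2(x_k, c_i)/D)} and, depending on
#' `scale_mode`, \eqn{w_g = \exp(-\Delta g^2 / G)} (`"balanced"`) or
#' \eqn{w_g = \exp(-(\Delta g / G)^2)} (`"printed"`). All factors lie in
#' (0, 1]; a pixel sitting exactly on a cluster's spatial centroid with
#' matching gray has similarity 1.
#'
#' @param dist spatial distance(s) `dis(x_k, c_i)`, pixel units.
#' @param gray_gap gray difference(s) `g(x_k) - g(c_i)`.
#' @param D,G positive adaptive scales (see [adaptive_scales()]).
#' @param scale_mode `"printed"` (default) or `"balanced"`.
#' @return A list with `sim`, `wd`, `wg`, shaped like the inputs.
#' @examples
#' # dis^2 = D and matching gray: similarity exp(-1)
#' pixel_cluster_similarity(2, 0, D = 4, G = 1)$sim
#' @export
pixel_cluster_similarity <- function(dist, gray_gap, D, G,
                                     scale_mode = c("printed", "balanced")) {
  scale_mode <- match.arg(scale_mode)
  if (min(D) <= 0 || min(G) <= 0) {
    stop("similarity scales must be positive", call. = FALSE)
  }
  lwd <- -dist^2 / D
  lwg <- if (scale_mode == "balanced") -gray_gap^2 / G else -(gray_gap / G)^2
  list(sim = exp(lwd + lwg), wd = exp(lwd), wg = exp(lwg),
       log_sim = lwd + lwg)
}

# Full similarity field for an image against a set of cluster states.
# Returns H x W x c arrays of sim / wd / wg plus the log-similarity used
# by the numerically safe membership update. `distance` selects how
# dis(x_k, c_i) is read: "gray" (default) is the pixel-to-center distance
# in gray space, "spatial" the distance between the pixel's coordinates
# and the cluster's membership-weighted spatial centroid. When
# `spatial = FALSE` the distance factor is dropped and the pure intensity
# kernel exp(-(g(x_k) - v_i)^2 / G) is used.
similarity_field <- function(image, clusters, scale_mode = "printed",
                             floor = 1e-12, spatial = TRUE,
                             distance = c("gray", "spatial")) {
  distance <- match.arg(distance)
  img <- as_gray_image(image)
  h <- nrow(img$pixels); w <- ncol(img$pixels)
  nc <- nrow(clusters)
  g <- as.vector(img$pixels)
  gap <- outer(g, clusters$gray, "-")          # n x c
  e <- gap^2
  if (spatial) {
    if (distance == "spatial") {
      rows <- rep(seq_len(h), times = w)
      cols <- rep(seq_len(w), each = h)
      d <- sqrt(outer(rows, clusters$row, "-")^2 +
                outer(cols, clusters$col, "-")^2)
    } else {
      d <- abs(gap)
    }
    sc <- adaptive_scales(array(d, c(h, w, nc)), array(e, c(h, w, nc)),
                          scale_mode = scale_mode, floor = floor)
    lwd <- -d^2 / as.vector(sc$D)
    lwg <- if (scale_mode == "balanced") -e / as.vector(sc$G)
           else -e / as.vector(sc$G)^2
  } else {
    em <- matrix(e, h * w, nc)
    G <- pmax(rowMeans(abs(em - rowMeans(em))), floor)
    sc <- list(D = NULL, G = array(G, c(h, w)))
    lwd <- matrix(0, h * w, nc)
    lwg <- -e / G
  }
  ls <- lwd + lwg
  list(sim = array(exp(ls), c(h, w, nc)),
       wd = array(exp(lwd), c(h, w, nc)),
       wg = array(exp(lwg), c(h, w, nc)),
       log_sim = array(ls, c(h, w, nc)),
       scales = sc)
}

#' Aggregate per-pixel similarity into the membership-update statistic
#'
#' The statistic \eqn{S_{ik}} driving the membership update. In
#' `"direct"` mode (default) it is the similarity itself. In
#' `"neighborhood"` mode it is a membership-weighted local average over
#' the (2 `window_radius` + 1)^2 window around each pixel,
#' \deqn{S_{ik} = \frac{\sum_{j \in N(k)} (u'_{ij})^m Sim(x_j, c_i)}
#'                     {\sum_{j \in N(k)} (u'_{ij})^m},}
#' which pools similarity evidence from a pixel's neighbors and damps
#' impulse noise. Windows are edge-replicated; a window with zero total
#' weight falls back to the direct value for that pixel.
#'
#' @param sim similarity array (H x W x c), entries in (0, 1].
#' @param u_prime membership stack (H x W x c), per-pixel normalized.
#' @param m fuzzifier exponent (> 1).
#' @param mode `"direct"` or `"neighborhood"`.
#' @param window_radius neighborhood half-width (default 1, a 3x3 window).
#' @return An H x W x c array with entries in (0, 1].
#' @export
aggregate_sik <- function(sim, u_prime = NULL, m = 2,
                          mode = c("direct", "neighborhood"),
                          window_radius = 1) {
  mode <- match.arg(mode)
  if (mode == "direct") return(sim)
  if (is.null(u_prime)) {
    stop("neighborhood aggregation needs the membership stack", call. = FALSE)
  }
  if (m <= 1) stop("fuzzifier `m` must exceed 1", call. = FALSE)
  d <- stack_dims(sim)
  out <- sim
  for (i in seq_len(d[3])) {
    wgt <- u_prime[, , i]^m
    num <- box_mean(wgt * sim[, , i], window_radius)
    den <- box_mean(wgt, window_radius)
    s <- num / den
    bad <- !is.finite(s) | den <= 0
    s[bad] <- sim[, , i][bad]
    out[, , i] <- s
  }
  out
}
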