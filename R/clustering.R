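#' Configuration for the IFCM-MS segmentation driver
#'
#' Collects every tunable of [ifcm_ms()]: cluster count, fuzzifier,
#' convergence threshold, iteration cap, seed, the three ablation
#' switches, and the sub-configurations of the generator, the membership
#' transfer model and the similarity measurement.
#'
#' @param clusters number of clusters `c` (>= 2).
#' @param m fuzzifier exponent (> 1, default 2).
#' @param eta convergence threshold on the max-abs change between
#'   consecutive post-transfer membership stacks (default `1e-5`).
#' @param max_iter iteration cap (default 100).
#' @param seed integer seed; all randomness of a run flows from it.
#' @param use_ifs enable the intuitionistic fuzzy membership
#'   \eqn{u' \propto u + \pi(u)} (default `TRUE`).
#' @param use_transfer enable the membership information transfer model
#'   (default `TRUE`).
#' @param use_similarity enable the gray/distance similarity; when
#'   `FALSE` the pure intensity kernel
#'   \eqn{\exp(-(g(x_k)-v_i)^2/G)} is used instead (default `TRUE`).
#' @param generator a [generator_params()] object (default Sugeno,
#'   lambda = 2).
#' @param transfer a [guided_filter_params()] object.
#' @param similarity list of similarity options: `mode` (`"direct"` or
#'   `"neighborhood"`), `window_radius`, `scale_floor`, `scale_mode`
#'   (`"balanced"` or `"printed"`), `distance` (`"gray"`, the default
#'   pixel-to-center distance in gray space, or `"spatial"`, the distance
#'   to the cluster's membership-weighted spatial centroid), and
#'   `fixed_G` (a fixed gray scale overriding the adaptive one;
#'   `NULL` = adaptive).
#' @param center_power_m if `TRUE` (default), raise the membership
#'   weights of the center update to the fuzzifier `m` (classical-FCM
#'   style), which keeps distinct centers from collapsing onto one
#'   another under the similarity-softmax update; `FALSE` uses plain
#'   `u'` weights.
#' @param init `"centers"` (default) or `"memberships"`; see [fcm()].
#'   The same seeding policy is used for both drivers so baseline
#'   comparisons are initialization-fair.
#' @return An object of class `ifcm_config`.
#' @export
ifcm_config <- function(clusters, m = 2, eta = 1e-5, max_iter = 100,
                        seed = 1, use_ifs = TRUE, use_transfer = TRUE,
                        use_similarity = TRUE,
                        generator = generator_params(),
                        transfer = guided_filter_params(),
                        similarity = list(), center_power_m = TRUE,
                        init = c("centers", "memberships")) {
  init <- match.arg(init)
  clusters <- as.integer(clusters)
  if (clusters < 2) stop("`clusters` must be >= 2", call. = FALSE)
  if (m <= 1) stop("fuzzifier `m` must exceed 1", call. = FALSE)
  if (eta <= 0) stop("`eta` must be positive", call. = FALSE)
  max_iter <- as.integer(max_iter)
  if (max_iter < 1) stop("`max_iter` must be >= 1", call. = FALSE)
  sim_defaults <- list(mode = "direct", window_radius = 1L,
                       scale_floor = 1e-12, scale_mode = "printed",
                       distance = "gray", fixed_G = NULL)
  unknown <- setdiff(names(similarity), names(sim_defaults))
  if (length(unknown)) {
    stop("unknown similarity option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sim <- utils::modifyList(sim_defaults, similarity)
  sim$mode <- match.arg(sim$mode, c("direct", "neighborhood"))
  sim$scale_mode <- match.arg(sim$scale_mode, c("balanced", "printed"))
  sim$distance <- match.arg(sim$distance, c("gray", "spatial"))
  structure(list(
    clusters = clusters, m = m, eta = eta, max_iter = max_iter,
    seed = as.integer(seed), use_ifs = isTRUE(use_ifs),
    use_transfer = isTRUE(use_transfer),
    use_similarity = isTRUE(use_similarity),
    generator = generator, transfer = transfer, similarity = sim,
    center_power_m = isTRUE(center_power_m), init = init
  ), class = "ifcm_config")
}

#' Membership update from the similarity statistic
#'
#' Minimizing the similarity-based objective under the per-pixel
#' sum-to-one constraint gives
#' \deqn{u'_{ik} = \frac{(1/S_{ik}^2)^{-1/(m-1)}}
#'                      {\sum_i (1/S_{ik}^2)^{-1/(m-1)}}
#'             = \frac{S_{ik}^{2/(m-1)}}{\sum_i S_{ik}^{2/(m-1)}}.}
#' The result is invariant to a per-pixel rescaling of `S`.
#'
#' @param S similarity statistic (H x W x c array, or n x c matrix),
#'   entries in `(0, 1]`.
#' @param m fuzzifier exponent (> 1).
#' @return A normalized membership stack shaped like `S`.
#' @export
membership_update <- function(S, m = 2) {
  if (m <= 1) stop("fuzzifier `m` must exceed 1", call. = FALSE)
  if (min(S) < 0) stop("`S` entries must be positive", call. = FALSE)
  d <- dim(S)
  nc <- d[length(d)]
  p <- matrix(S^(2 / (m - 1)), ncol = nc)
  tot <- rowSums(p)
  if (any(tot <= 0)) {
    stop("membership_update: a pixel has zero similarity to every cluster ",
         "(similarity scale underflow)", call. = FALSE)
  }
  array(p / tot, dim = d)
}

#' Cluster center update
#'
#' Gray centers are membership-weighted means of the pixel intensities,
#' \deqn{v_i = \frac{\sum_k w_{ik} x_k}{\sum_k w_{ik}},}
#' with `w = u'` by default (`power = 1`) or `w = u'^m`
#' (classical-FCM weighting). The spatial centroid `(row, col)` of each
#' cluster is computed with the same weights over the pixel coordinates
#' and feeds the distance-similarity term.
#'
#' @param u_prime membership stack (H x W x c).
#' @param image a [gray_image()] or numeric matrix.
#' @param power exponent on the weights (1 or the fuzzifier `m`).
#' @return A [cluster_states()] data frame. A cluster with zero total
#'   weight is re-seeded to a random pixel (with a message).
#' @export
center_update <- function(u_prime, image, power = 1) {
  img <- as_gray_image(image)
  d <- stack_dims(u_prime)
  h <- d[1]; w <- d[2]; nc <- d[3]
  g <- as.vector(img$pixels)
  rows <- rep(seq_len(h), times = w)
  cols <- rep(seq_len(w), each = h)
  W <- matrix(u_prime, h * w, nc)
  if (power != 1) W <- W^power
  tot <- colSums(W)
  gray <- numeric(nc); crow <- numeric(nc); ccol <- numeric(nc)
  for (i in seq_len(nc)) {
    if (tot[i] <= 0) {
      k <- sample.int(h * w, 1L)
      message(sprintf(
        "center_update: cluster %d collapsed; re-seeded to pixel %d", i, k))
      gray[i] <- g[k]; crow[i] <- rows[k]; ccol[i] <- cols[k]
    } else {
      gray[i] <- sum(W[, i] * g) / tot[i]
      crow[i] <- sum(W[, i] * rows) / tot[i]
      ccol[i] <- sum(W[, i] * cols) / tot[i]
    }
  }
  cluster_states(gray, crow, ccol)
}

#' Clustering objective with intuitionistic fuzzy entropy
#'
#' The monitored objective
#' \deqn{J = \sum_i \sum_k (u'_{ik})^m / S_{ik}^2 +
#'       \sum_i \pi'_i e^{1 - \pi'_i},}
#' i.e. the similarity-based clustering cost plus the intuitionistic
#' fuzzy entropy of the hesitation maps (zero when `pi` is `NULL`). The
#' entropy term is monitored only; it does not enter the membership
#' update.
#'
#' @param u_prime membership stack (H x W x c).
#' @param S similarity statistic, same shape, entries in (0, 1].
#' @param pi hesitation stack (same shape) or `NULL`.
#' @param m fuzzifier exponent.
#' @return A finite scalar.
#' @export
objective_value <- function(u_prime, S, pi = NULL, m = 2) {
  S <- pmax(S, 1e-154)
  J <- sum((u_prime^m) / (S * S))
  if (!is.null(pi)) J <- J + hesitation_entropy(pi)
  J
}

new_segmentation_result <- function(labels, u, centers, trace, deltas,
                                    iterations, converged, method, config) {
  structure(list(
    labels = labels, memberships = u, centers = centers,
    objective_trace = trace, membership_deltas = deltas,
    iterations = iterations, converged = converged,
    method = method, config = config
  ), class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf(
    "<segmentation_result> %s: %d x %d pixels, %d clusters, %d iteration(s), %s\n",
    x$method, nrow(x$labels), ncol(x$labels), nrow(x$centers),
    x$iterations, if (x$converged) "converged" else "NOT converged"))
  cat("centers (gray):", paste(sprintf("%.2f", x$centers$gray),
                               collapse = ", "), "\n")
  invisible(x)
}

stack_labels <- function(u) {
  d <- stack_dims(u)
  matrix(max.col(matrix(u, d[1] * d[2], d[3]), ties.method = "first"),
         d[1], d[2])
}

# Eq. (5)-style inverse-power memberships from intensity distances, with
# zero-distance pixels assigned crisp membership to the first matching
# center.
fcm_memberships <- function(g, centers, m) {
  d2 <- outer(g, centers, "-")^2
  zero <- d2 <= 0
  pwr <- d2^(-1 / (m - 1))
  u <- pwr / rowSums(pwr)
  sing <- rowSums(zero) > 0
  if (any(sing)) {
    u[sing, ] <- 0
    first0 <- max.col(zero[sing, , drop = FALSE], ties.method = "first")
    u[cbind(which(sing), first0)] <- 1
  }
  u
}

#' Classical fuzzy C-means segmentation (baseline)
#'
#' Intensity-based FCM: memberships are inverse-power distances to the
#' gray centers,
#' \deqn{u_{ik} = \frac{\|x_k - c_i\|^{-2/(m-1)}}
#'                     {\sum_j \|x_k - c_j\|^{-2/(m-1)}},}
#' and centers are `u^m`-weighted intensity means. The loop alternates
#' center and membership updates from a seeded random initial membership
#' matrix until the max-abs membership change falls below `eta` or
#' `max_iter` is reached. A pixel coinciding exactly with a center gets
#' membership 1 there (standard singularity handling).
#'
#' @param image a [gray_image()] or numeric matrix (non-constant).
#' @param clusters number of clusters (>= 2).
#' @param m fuzzifier exponent (default 2).
#' @param eta convergence threshold (default `1e-5`).
#' @param max_iter iteration cap (default 100).
#' @param seed integer seed for the random initialization.
#' @param init `"centers"` (default) seeds the run from k-means++-style
#'   random initial gray centers (a uniformly drawn pixel, then pixels
#'   drawn with probability proportional to their squared gray distance
#'   to the nearest chosen center), which reliably spreads the initial
#'   centers across the image's intensity modes; `"memberships"` draws
#'   per-pixel normalized-uniform random memberships, whose initial
#'   centers all start near the global mean.
#' @param init_u optional explicit initial membership stack (H x W x c);
#'   overrides the random initialization.
#' @return A `segmentation_result` with 1-based `labels`, final
#'   `memberships`, `centers`, the objective trace
#'   \eqn{J_f = \sum (u_{ik})^m d^2(x_k, c_i)}, per-iteration membership
#'   deltas, and convergence information.
#' @export
fcm <- function(image, clusters, m = 2, eta = 1e-5, max_iter = 100,
                seed = 1, init = c("centers", "memberships"),
                init_u = NULL) {
  init <- match.arg(init)
  img <- as_gray_image(image)
  if (max(img$pixels) == min(img$pixels)) {
    stop("constant image: no partition exists", call. = FALSE)
  }
  clusters <- as.integer(clusters)
  if (clusters < 2) stop("`clusters` must be >= 2", call. = FALSE)
  h <- nrow(img$pixels); w <- ncol(img$pixels); n <- h * w
  g <- as.vector(img$pixels)
  with_seed(seed, {
    u <- if (!is.null(init_u)) {
      check_membership_stack(init_u)
      matrix(init_u, n, clusters)
    } else if (init == "centers") {
      fcm_memberships(g, seed_centers_pp(g, clusters), m)
    } else {
      matrix(random_membership_stack(h, w, clusters), n, clusters)
    }
    trace <- numeric(0); deltas <- numeric(0)
    converged <- FALSE; it <- 0L
    centers <- numeric(clusters)
    while (it < max_iter) {
      it <- it + 1L
      um <- u^m
      tot <- colSums(um)
      for (i in seq_len(clusters)) {
        if (tot[i] <= 0) {
          k <- sample.int(n, 1L)
          message(sprintf("fcm: cluster %d collapsed; re-seeded to pixel %d",
                          i, k))
          centers[i] <- g[k]
        } else {
          centers[i] <- sum(um[, i] * g) / tot[i]
        }
      }
      u_new <- fcm_memberships(g, centers, m)
      trace <- c(trace, sum((u_new^m) * outer(g, centers, "-")^2))
      delta <- max(abs(u_new - u))
      deltas <- c(deltas, delta)
      u <- u_new
      if (delta <= eta) { converged <- TRUE; break }
    }
    stack <- array(u, c(h, w, clusters))
    new_segmentation_result(
      labels = stack_labels(stack), u = stack,
      centers = cluster_states(centers), trace = trace, deltas = deltas,
      iterations = it, converged = converged, method = "fcm",
      config = list(clusters = clusters, m = m, eta = eta,
                    max_iter = max_iter, seed = seed))
  })
}

#' IFCM-MS segmentation
#'
#' Intuitionistic fuzzy C-means with membership information transfer and
#' the adaptive gray/distance similarity measurement. Each iteration:
#' \enumerate{
#'   \item adaptive scales and similarity `Sim(x_k, c_i)` from the current
#'     cluster states (or the pure intensity kernel when
#'     `use_similarity = FALSE`);
#'   \item the aggregate statistic `S_ik` ([aggregate_sik()]);
#'   \item membership update ([membership_update()]);
#'   \item center update ([center_update()]);
#'   \item intuitionistic membership `u' = normalize(u + pi(u))` when
#'     `use_ifs`;
#'   \item membership transfer ([transfer_membership()]) guided by the
#'     previous iteration's stack when `use_transfer`;
#'   \item convergence check: max-abs difference between consecutive
#'     post-transfer stacks against `eta`.
#' }
#' The run is deterministic given `config$seed`. Non-convergence at
#' `max_iter` returns a result with `converged = FALSE` rather than an
#' error; a constant image is rejected.
#'
#' @param image a [gray_image()] or numeric matrix.
#' @param config an [ifcm_config()] object.
#' @param init_u optional explicit initial membership stack (H x W x c);
#'   overrides the configured initialization.
#' @return A `segmentation_result` (see [fcm()]) whose
#'   `membership_deltas` and `normalization_error` record the
#'   per-iteration max-abs membership change and the worst per-pixel
#'   deviation of the membership sums from 1.
#' @export
ifcm_ms <- function(image, config, init_u = NULL) {
  if (!inherits(config, "ifcm_config")) {
    stop("`config` must be created with ifcm_config()", call. = FALSE)
  }
  img <- as_gray_image(image)
  if (max(img$pixels) == min(img$pixels)) {
    stop("constant image: no partition exists", call. = FALSE)
  }
  h <- nrow(img$pixels); w <- ncol(img$pixels)
  nc <- config$clusters; m <- config$m
  sim_cfg <- config$similarity
  cpow <- if (config$center_power_m) m else 1
  with_seed(config$seed, {
    u_prev <- if (!is.null(init_u)) {
      check_membership_stack(init_u)
      init_u
    } else if (config$init == "centers") {
      c0 <- cluster_states(seed_centers_pp(as.vector(img$pixels), nc))
      sf0 <- ifcm_similarity(img, c0, sim_cfg, spatial = FALSE)
      ls0 <- matrix(sf0$log_sim, h * w, nc)
      membership_update(array(exp(ls0 - row_max(ls0)), c(h, w, nc)), m)
    } else {
      random_membership_stack(h, w, nc)
    }
    centers <- center_update(u_prev, img, power = cpow)
    trace <- numeric(0); deltas <- numeric(0); norm_err <- numeric(0)
    converged <- FALSE; it <- 0L
    u <- u_prev
    while (it < config$max_iter) {
      it <- it + 1L
      sf <- ifcm_similarity(img, centers, sim_cfg,
                            spatial = config$use_similarity)
      if (sim_cfg$mode == "direct") {
        # shift log-similarities per pixel so the largest is 1: the
        # membership update is invariant to per-pixel scaling of S and
        # this avoids underflow of exp() for distant clusters
        ls <- matrix(sf$log_sim, h * w, nc)
        S_upd <- array(exp(ls - row_max(ls)), c(h, w, nc))
        S_obj <- pmax(sf$sim, 1e-154)
      } else {
        S_obj <- aggregate_sik(pmax(sf$sim, 1e-154), u_prev, m = m,
                               mode = "neighborhood",
                               window_radius = sim_cfg$window_radius)
        S_upd <- S_obj
      }
      u <- membership_update(S_upd, m)
      centers <- center_update(u, img, power = cpow)
      pi_map <- NULL
      if (config$use_ifs) {
        tr <- intuitionify(u, config$generator)
        pi_map <- tr$pi
        u <- normalize_stack(u + pi_map, zero_to_uniform = FALSE)
      }
      if (config$use_transfer) {
        u <- transfer_membership(u_prev, u, config$transfer)
      }
      trace <- c(trace, objective_value(u, S_obj, pi_map, m))
      norm_err <- c(norm_err,
                    max(abs(rowSums(matrix(u, h * w, nc)) - 1)))
      delta <- max(abs(u - u_prev))
      deltas <- c(deltas, delta)
      u_prev <- u
      if (delta <= config$eta) { converged <- TRUE; break }
    }
    res <- new_segmentation_result(
      labels = stack_labels(u), u = u, centers = centers, trace = trace,
      deltas = deltas, iterations = it, converged = converged,
      method = "ifcm_ms", config = config)
    res$normalization_error <- norm_err
    res
  })
}

# Similarity field honoring the config's fixed_G override.
ifcm_similarity <- function(img, centers, sim_cfg, spatial) {
  if (!is.null(sim_cfg$fixed_G) && !spatial) {
    e <- outer(as.vector(img$pixels), centers$gray, "-")^2
    ls <- -e / sim_cfg$fixed_G
    h <- nrow(img$pixels); w <- ncol(img$pixels)
    return(list(sim = array(exp(ls), c(h, w, nrow(centers))),
                log_sim = array(ls, c(h, w, nrow(centers)))))
  }
  similarity_field(img, centers, scale_mode = sim_cfg$scale_mode,
                   floor = sim_cfg$scale_floor, spatial = spatial,
                   distance = sim_cfg$distance)
}
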