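# Independent brute-force oracles used to cross-check the vectorized
# implementations. These deliberately use naive per-element loops.

clampi <- function(i, n) pmin(pmax(i, 1L), n)

# Gather the replicate-padded window around (i, j) of matrix x.
window_vals <- function(x, i, j, r) {
  v <- numeric((2 * r + 1)^2)
  n <- 0L
  for (di in -r:r) for (dj in -r:r) {
    n <- n + 1L
    v[n] <- x[clampi(i + di, nrow(x)), clampi(j + dj, ncol(x))]
  }
  v
}

brute_median_filter <- function(x, r) {
  out <- x
  for (i in seq_len(nrow(x))) for (j in seq_len(ncol(x))) {
    out[i, j] <- stats::median(window_vals(x, i, j, r))
  }
  out
}

brute_guided_filter <- function(p, guide, r, eps) {
  h <- nrow(p); w <- ncol(p)
  a <- matrix(0, h, w); b <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    Iv <- window_vals(guide, i, j, r)
    pv <- window_vals(p, i, j, r)
    mI <- mean(Iv); mp <- mean(pv)
    varI <- mean(Iv * Iv) - mI^2
    cov <- mean(Iv * pv) - mI * mp
    ak <- if (varI + eps == 0) 0 else cov / (varI + eps)
    a[i, j] <- ak
    b[i, j] <- mp - ak * mI
  }
  q <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    q[i, j] <- mean(window_vals(a, i, j, r)) * guide[i, j] +
      mean(window_vals(b, i, j, r))
  }
  q
}

# Naive classical FCM: explicit loops over the center and membership
# update formulas, same alternation order and stopping rule as fcm().
brute_fcm <- function(g, init_u, m = 2, eta = 1e-5, max_iter = 100) {
  u <- init_u
  nc <- ncol(u)
  centers <- numeric(nc)
  for (it in seq_len(max_iter)) {
    for (i in seq_len(nc)) {
      centers[i] <- sum(u[, i]^m * g) / sum(u[, i]^m)
    }
    u_new <- matrix(0, nrow(u), nc)
    for (k in seq_along(g)) {
      d <- abs(g[k] - centers)
      if (any(d == 0)) {
        u_new[k, which(d == 0)[1]] <- 1
      } else {
        wk <- d^(-2 / (m - 1))
        u_new[k, ] <- wk / sum(wk)
      }
    }
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta <= eta) break
  }
  list(u = u, centers = centers, iterations = it)
}

# Small two-value test image with a seeded random split.
two_value_image <- function(h = 16, w = 16, lo = 10, hi = 200, seed = 1) {
  withr::with_seed(seed, {
    px <- matrix(lo, h, w)
    px[sample.int(h * w, floor(h * w / 3))] <- hi
    gray_image(px)
  })
}

# Small phantom fixture for driver tests.
small_phantom <- function(seed = 1, shape = c(48, 48), sd = 4) {
  make_phantom(phantom_spec(shape = shape, class_noise_sd = sd, seed = seed))
}
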