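# Internal numerics shared across modules: seeded evaluation, membership
# stack helpers, replicate padding, box sums and fast median filtering.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

# A membership stack is an H x W x c array, nonnegative, summing to 1 over
# the third margin at every pixel.
stack_dims <- function(u) {
  d <- dim(u)
  if (is.null(d) || length(d) != 3) {
    stop("membership stack must be an H x W x c array", call. = FALSE)
  }
  d
}

check_membership_stack <- function(u, tol = 1e-9) {
  d <- stack_dims(u)
  if (d[3] < 1) stop("membership stack needs at least one cluster", call. = FALSE)
  if (min(u) < -tol || max(u) > 1 + tol) {
    stop("membership values must lie in [0, 1]", call. = FALSE)
  }
  s <- rowSums(matrix(u, d[1] * d[2], d[3]))
  if (max(abs(s - 1)) > tol) {
    stop("membership stack is not normalized per pixel", call. = FALSE)
  }
  invisible(u)
}

# Renormalize so each pixel's memberships sum to 1; pixels whose total is
# (numerically) zero fall back to the uniform 1/c assignment.
normalize_stack <- function(u, zero_to_uniform = TRUE) {
  d <- stack_dims(u)
  m <- matrix(u, d[1] * d[2], d[3])
  s <- rowSums(m)
  bad <- s <= 0
  if (any(bad)) {
    if (!zero_to_uniform) stop("all-zero membership row", call. = FALSE)
    m[bad, ] <- 1 / d[3]
    s[bad] <- 1
  }
  array(m / s, dim = d)
}

# Seeded per-pixel random memberships: independent uniforms normalized to
# sum 1 across clusters at each pixel.
random_membership_stack <- function(h, w, c) {
  u <- array(stats::runif(h * w * c), dim = c(h, w, c))
  normalize_stack(u, zero_to_uniform = FALSE)
}

# Seeded k-means++-style center seeding on intensities: the first center
# is a uniformly drawn pixel's gray value, each further center a pixel
# drawn with probability proportional to its squared gray distance to
# the nearest center chosen so far. Draws from the caller's RNG stream.
seed_centers_pp <- function(g, c) {
  centers <- numeric(c)
  centers[1] <- g[sample.int(length(g), 1L)]
  d2 <- (g - centers[1])^2
  for (i in seq_len(c - 1L)) {
    if (max(d2) <= 0) {
      centers[i + 1L] <- g[sample.int(length(g), 1L)]
    } else {
      centers[i + 1L] <- g[sample.int(length(g), 1L, prob = d2)]
    }
    d2 <- pmin(d2, (g - centers[i + 1L])^2)
  }
  centers
}

# Replicate-pad a matrix by `r` pixels on every side.
pad_replicate <- function(x, r) {
  h <- nrow(x); w <- ncol(x)
  x[c(rep(1L, r), seq_len(h), rep(h, r)),
    c(rep(1L, r), seq_len(w), rep(w, r)), drop = FALSE]
}

# Column-wise cumulative sums without per-column R calls: cumsum the
# flattened matrix and subtract the running offset at column starts.
col_cumsum <- function(m) {
  n <- nrow(m)
  cs <- matrix(cumsum(m), n, ncol(m))
  if (ncol(m) > 1) {
    off <- c(0, cs[n, -ncol(m)])
    cs <- cs - rep(off, each = n)
  }
  cs
}

# Column-wise running sums of window length `w` along rows.
run_sum_rows <- function(m, w) {
  cs <- col_cumsum(m)
  top <- cs[w:nrow(m), , drop = FALSE]
  if (w < nrow(m)) {
    bot <- rbind(matrix(0, 1, ncol(m)), cs[seq_len(nrow(m) - w), , drop = FALSE])
  } else {
    bot <- matrix(0, 1, ncol(m))
  }
  top - bot
}

# Row-wise maxima of a matrix via vectorized pairwise maxima.
row_max <- function(m) {
  out <- m[, 1]
  for (j in seq_len(ncol(m))[-1]) out <- pmax(out, m[, j])
  out
}

# Mean over the (2r+1)^2 replicate-padded window centered at every pixel.
box_mean <- function(x, r) {
  if (r < 1) return(x)
  xp <- pad_replicate(x, r)
  w <- 2L * r + 1L
  t(run_sum_rows(t(run_sum_rows(xp, w)), w)) / (w * w)
}

# Vectorized median-of-9 selection network (Paeth). `cols` is a list of 9
# equal-length numeric vectors; returns the elementwise median.
median9 <- function(cols) {
  p <- cols
  sort2 <- function(i, j) {
    lo <- pmin(p[[i]], p[[j]]); hi <- pmax(p[[i]], p[[j]])
    p[[i]] <<- lo; p[[j]] <<- hi
  }
  sort2(2, 3); sort2(5, 6); sort2(8, 9)
  sort2(1, 2); sort2(4, 5); sort2(7, 8)
  sort2(2, 3); sort2(5, 6); sort2(8, 9)
  sort2(1, 4); sort2(6, 9); sort2(5, 8)
  sort2(4, 7); sort2(2, 5); sort2(3, 6)
  sort2(5, 8); sort2(5, 3); sort2(7, 5)
  sort2(5, 3)
  p[[5]]
}

# Gather the (2r+1)^2 shifted copies of the replicate-padded matrix as a
# list of vectors (window element per offset, for every center pixel).
window_shifts <- function(x, r) {
  h <- nrow(x); w <- ncol(x)
  xp <- pad_replicate(x, r)
  out <- vector("list", (2L * r + 1L)^2)
  n <- 0L
  for (dj in -r:r) {
    for (di in -r:r) {
      n <- n + 1L
      out[[n]] <- as.vector(xp[(1 + r + di):(h + r + di),
                               (1 + r + dj):(w + r + dj), drop = FALSE])
    }
  }
  out
}
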