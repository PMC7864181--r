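test_that("median filter: constants, impulses, and the brute-force oracle", {
  expect_equal(median_filter(matrix(0.3, 5, 5), 1), matrix(0.3, 5, 5))
  imp <- matrix(0, 5, 5); imp[3, 3] <- 1
  expect_equal(median_filter(imp, 1), matrix(0, 5, 5))
  withr::with_seed(8, {
    for (r in 1:2) {
      x <- matrix(runif(49), 7, 7)
      expect_equal(median_filter(x, r), brute_median_filter(x, r))
    }
  })
  expect_error(median_filter(matrix(0, 3, 3), 0), ">= 1")
})

test_that("median filter output range is contained in the input range", {
  withr::with_seed(9, {
    x <- matrix(rnorm(64), 8, 8)
    y <- median_filter(x, 1)
    expect_gte(min(y), min(x))
    expect_lte(max(y), max(x))
  })
})

test_that("guided filter matches the per-window brute-force evaluation", {
  withr::with_seed(10, {
    for (r in c(1, 2)) for (eps in c(0, 0.01)) {
      p <- matrix(runif(64), 8, 8)
      I <- matrix(runif(64), 8, 8)
      got <- guided_filter(p, I, guided_filter_params(radius = r, eps = eps))
      expect_lt(max(abs(got - brute_guided_filter(p, I, r, eps))), 1e-10)
    }
  })
})

test_that("guided filter limits: constant inputs and huge regularization", {
  p <- matrix(0.5, 8, 8)
  expect_equal(guided_filter(p, p, guided_filter_params(2, 0)), p)
  withr::with_seed(11, {
    p <- matrix(runif(64), 8, 8); I <- matrix(runif(64), 8, 8)
    q <- guided_filter(p, I, guided_filter_params(2, 1e12))
    bm <- ifcmms:::box_mean(ifcmms:::box_mean(p, 2), 2)
    expect_lt(max(abs(q - bm)), 1e-9)
  })
})

test_that("with eps = 0 and p = I the filter reproduces the guide", {
  withr::with_seed(12, {
    I <- matrix(runif(100), 10, 10)
    q <- guided_filter(I, I, guided_filter_params(radius = 2, eps = 0))
    expect_lt(max(abs(q - I)), 1e-8)
  })
})

test_that("subsampled fast path approximates the exact path on smooth maps", {
  withr::with_seed(13, {
    base <- outer(seq(0, 1, length.out = 32), seq(0, 1, length.out = 32),
                  function(a, b) 0.5 + 0.3 * sin(2 * a) * cos(2 * b))
    p <- base + matrix(rnorm(1024, 0, 0.01), 32, 32)
    q1 <- guided_filter(p, base, guided_filter_params(radius = 4, eps = 0.01))
    q2 <- guided_filter(p, base, guided_filter_params(radius = 4, eps = 0.01,
                                                      subsample = 2))
    expect_lt(max(abs(q1 - q2)), 0.05)
  })
})

test_that("guided filter parameter validation", {
  expect_error(guided_filter_params(radius = 0), ">= 1")
  expect_error(guided_filter_params(eps = -1), ">= 0")
  expect_error(guided_filter_params(subsample = 0), ">= 1")
  expect_error(guided_filter(matrix(0, 3, 3), matrix(0, 4, 4)),
               "identical shape")
})

test_that("membership transfer returns a normalized stack in [0, 1]", {
  # hard two-cluster stack with a straight boundary
  u <- array(0, c(8, 8, 2)); u[, 1:4, 1] <- 1; u[, , 2] <- 1 - u[, , 1]
  out <- transfer_membership(u, u, guided_filter_params(1, 0))
  sums <- rowSums(matrix(out, 64, 2))
  expect_lt(max(abs(sums - 1)), 1e-12)
  expect_gte(min(out), 0)
  expect_lte(max(out), 1)
})

test_that("the uniform membership stack is a fixed point of the transfer", {
  u <- array(0.25, c(6, 6, 4))
  out <- transfer_membership(u, u, guided_filter_params())
  expect_equal(out, u, tolerance = 1e-12)
})

test_that("an isolated flipped pixel is pulled back toward its region", {
  u_pre <- array(0, c(5, 5, 2)); u_pre[, , 1] <- 0.9; u_pre[, , 2] <- 0.1
  u_cur <- u_pre
  u_cur[3, 3, 1] <- 0.1; u_cur[3, 3, 2] <- 0.9
  out <- transfer_membership(u_pre, u_cur,
                             guided_filter_params(radius = 1, eps = 0.01))
  expect_lt(abs(out[3, 3, 1] - 0.9), abs(u_cur[3, 3, 1] - 0.9))
  expect_gt(out[3, 3, 1], 0.5)  # flipped pixel rejoins its region
})

test_that("transfer requires matching stack shapes", {
  expect_error(transfer_membership(array(0.5, c(4, 4, 2)),
                                   array(0.5, c(4, 5, 2))), "shape")
})
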