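test_that("membership update reproduces the closed form and its limits", {
  S <- array(c(0.8, 0.4), c(1, 1, 2))
  u <- membership_update(S, m = 2)
  expect_equal(as.vector(u), c(0.64, 0.16) / 0.8)  # (0.8, 0.2)
  # equal similarities: uniform 1/c
  u2 <- membership_update(array(0.3, c(2, 2, 4)), m = 2)
  expect_equal(as.vector(u2), rep(0.25, 16))
  # one similarity vanishing: crisp membership in the limit
  u3 <- membership_update(array(c(1, 1e-12), c(1, 1, 2)), m = 2)
  expect_lt(as.vector(u3)[2], 1e-20)
  expect_error(membership_update(array(0, c(1, 1, 2))), "zero similarity")
  expect_error(membership_update(array(0.5, c(1, 1, 2)), m = 1), "exceed 1")
})

test_that("center update: uniform, hard, and fractional weights", {
  img <- matrix(c(100, 0, 50, 150), 2, 2)
  u_unif <- array(0.5, c(2, 2, 2))
  cs <- center_update(u_unif, img)
  expect_equal(cs$gray, rep(mean(img), 2))
  expect_equal(cs$row, rep(1.5, 2))
  expect_equal(cs$col, rep(1.5, 2))
  # hard memberships give the class means
  u_hard <- array(0, c(2, 2, 2))
  u_hard[, , 1] <- matrix(c(1, 0, 0, 0), 2, 2)
  u_hard[, , 2] <- 1 - u_hard[, , 1]
  cs2 <- center_update(u_hard, img)
  expect_equal(cs2$gray, c(100, mean(c(0, 50, 150))))
  # weights (0.8, 0.2) on grays (100, 0): v = 80
  u_frac <- array(0, c(1, 2, 2))
  u_frac[1, , 1] <- c(0.8, 0.2); u_frac[1, , 2] <- c(0.2, 0.8)
  cs3 <- center_update(u_frac, matrix(c(100, 0), 1, 2))
  expect_equal(cs3$gray[1], 80)
})

test_that("objective value: uniform, hard, and entropy additivity", {
  n <- 36
  S1 <- array(1, c(6, 6, 2))
  u_unif <- array(0.5, c(6, 6, 2))
  expect_equal(objective_value(u_unif, S1, m = 2), n / 2)
  u_hard <- array(0, c(6, 6, 2)); u_hard[, , 1] <- 1
  expect_equal(objective_value(u_hard, S1, m = 2), n)
  pi <- array(0.2, c(6, 6, 2))
  expect_equal(objective_value(u_hard, S1, pi = pi, m = 2),
               n + hesitation_entropy(pi))
})

test_that("fcm fixed point: centers at the image's two values stay put", {
  img <- two_value_image(seed = 21)
  # crisp init at the generating partition
  u0 <- array(0, c(16, 16, 2))
  u0[, , 1] <- (img$pixels == 10) * 1
  u0[, , 2] <- 1 - u0[, , 1]
  res <- fcm(img, 2, init_u = u0)
  expect_equal(sort(res$centers$gray), c(10, 200), tolerance = 1e-6)
  expect_true(res$converged)
})

test_that("uniform membership init yields first centers at the image mean", {
  img <- two_value_image(seed = 22)
  u0 <- array(0.5, c(16, 16, 2))
  res <- suppressMessages(fcm(img, 2, init_u = u0, max_iter = 1))
  expect_equal(res$centers$gray, rep(mean(img$pixels), 2))
})

test_that("fcm objective is non-increasing and recovers two-value centers", {
  for (seed in c(1, 2, 3)) {
    img <- two_value_image(seed = seed)
    res <- fcm(img, 2, seed = seed)
    expect_true(all(diff(res$objective_trace) <= 1e-8))
    expect_equal(sort(res$centers$gray), c(10, 200), tolerance = 1.0)
  }
})

test_that("fcm rejects constant images and tiny cluster counts", {
  expect_error(fcm(matrix(7, 4, 4), 2), "constant image")
  expect_error(fcm(matrix(1:16, 4, 4), 1), ">= 2")
})

test_that("ifcm_ms is deterministic given the seed", {
  ph <- small_phantom(seed = 30)
  img <- salt_and_pepper(ph$image, 0.02, seed = 31)
  cfg <- ifcm_config(4, seed = 77, max_iter = 25)
  r1 <- ifcm_ms(img, cfg)
  r2 <- ifcm_ms(img, cfg)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$memberships, r2$memberships)
  expect_identical(r1$objective_trace, r2$objective_trace)
})

test_that("ifcm_ms labels are invariant (up to relabeling) under permutation
           of the initial cluster order", {
  ph <- small_phantom(seed = 32)
  cfg <- ifcm_config(3, seed = 5, max_iter = 30, use_transfer = FALSE)
  u0 <- withr::with_seed(40, ifcmms:::random_membership_stack(48, 48, 3))
  perm <- c(2L, 3L, 1L)
  r1 <- ifcm_ms(ph$image, cfg, init_u = u0)
  r2 <- ifcm_ms(ph$image, cfg, init_u = u0[, , perm])
  expect_identical(as.vector(r1$labels), perm[as.vector(r2$labels)])
})

test_that("memberships stay normalized through every iteration", {
  ph <- small_phantom(seed = 33)
  img <- salt_and_pepper(ph$image, 0.02, seed = 34)
  res <- ifcm_ms(img, ifcm_config(4, seed = 1, max_iter = 15))
  expect_lt(max(res$normalization_error), 1e-9)
  expect_equal(length(res$normalization_error), res$iterations)
})

test_that("with transfer disabled the loop terminates below eta", {
  for (seed in c(1, 2)) {
    ph <- small_phantom(seed = seed)
    res <- ifcm_ms(ph$image,
                   ifcm_config(4, seed = seed, use_transfer = FALSE))
    expect_true(res$converged)
    expect_lte(res$iterations, 100)
    expect_lte(res$membership_deltas[res$iterations], 1e-5)
  }
})

test_that("intensity-only reduction reaches the classical FCM fixed point", {
  img <- two_value_image(seed = 23)
  cfg <- ifcm_config(2, seed = 3, use_ifs = FALSE, use_transfer = FALSE,
                     use_similarity = FALSE,
                     similarity = list(fixed_G = 400))
  res <- ifcm_ms(img, cfg)
  oracle <- fcm(img, 2, seed = 3)
  expect_equal(sort(res$centers$gray), sort(oracle$centers$gray),
               tolerance = 1e-6)
})

test_that("a clean two-blob phantom is recovered exactly (transfer off) and
           near-exactly under full defaults", {
  rows <- matrix(1:48, 48, 48); cols <- t(rows)
  disc <- (rows - 24)^2 + (cols - 30)^2 <= 64
  px <- matrix(40, 48, 48); px[disc] <- 200
  for (seed in 1:5) {
    r0 <- ifcm_ms(gray_image(px),
                  ifcm_config(2, seed = seed, use_transfer = FALSE))
    expect_identical(r0$labels == which.max(r0$centers$gray), disc)
    # the median prefilter of the transfer model rounds the few convex
    # corner pixels of the discretized disc; everything else is exact
    rf <- ifcm_ms(gray_image(px), ifcm_config(2, seed = seed, max_iter = 60))
    acc <- mean((rf$labels == which.max(rf$centers$gray)) == disc)
    expect_gte(acc, 0.995)
  }
})

test_that("non-convergence is reported, not thrown", {
  ph <- small_phantom(seed = 35)
  res <- ifcm_ms(ph$image, ifcm_config(4, seed = 2, max_iter = 2))
  expect_false(res$converged)
  expect_identical(res$iterations, 2L)
  expect_error(ifcm_ms(matrix(3, 8, 8), ifcm_config(2)), "constant image")
})

test_that("final labels break membership ties toward the lowest cluster", {
  u <- array(0.5, c(2, 2, 2))
  expect_true(all(ifcmms:::stack_labels(u) == 1L))
})
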