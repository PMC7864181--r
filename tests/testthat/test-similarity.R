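test_that("adaptive scales are mean absolute deviations across clusters", {
  d <- array(c(1, 2, 3), c(1, 1, 3))
  sc <- adaptive_scales(d, d^2, scale_mode = "printed")
  expect_equal(as.vector(sc$D), (1 + 0 + 1) / 3)
  # squared gray gaps {0, 4}: deviations |0-2|, |4-2| -> G = 2
  e <- array(c(0, 4), c(1, 1, 2))
  sc2 <- adaptive_scales(sqrt(e), e, scale_mode = "printed")
  expect_equal(as.vector(sc2$G), 2)
})

test_that("degenerate equal dissimilarities floor to the scale floor", {
  d <- array(5, c(1, 1, 3))
  sc <- adaptive_scales(d, d, scale_mode = "printed")
  expect_equal(as.vector(sc$D), 1e-12)
  expect_equal(as.vector(sc$G), 1e-12)
})

test_that("fewer than two clusters is a configuration error", {
  d <- array(1, c(2, 2, 1))
  expect_error(adaptive_scales(d, d), "2 clusters")
})

test_that("similarity factors follow the exponential kernels", {
  # coincident pixel: both exponents zero
  expect_equal(pixel_cluster_similarity(0, 0, D = 1, G = 1)$sim, 1)
  # dis^2 = D with equal grays: exp(-1)
  expect_equal(pixel_cluster_similarity(2, 0, D = 4, G = 1)$sim, exp(-1))
  # dis^2 = D and (dg/G)^2 = 1: product of factors exp(-2)
  s <- pixel_cluster_similarity(2, 3, D = 4, G = 3, scale_mode = "printed")
  expect_equal(s$sim, exp(-2))
  expect_equal(s$wd * s$wg, s$sim)
  expect_error(pixel_cluster_similarity(1, 1, D = 0, G = 1), "positive")
})

test_that("similarity strictly decreases in each dissimilarity separately", {
  dist <- seq(0, 5, by = 0.5)
  s_d <- pixel_cluster_similarity(dist, 1, D = 2, G = 3)$sim
  expect_true(all(diff(s_d) < 0))
  gap <- seq(0, 5, by = 0.5)
  s_g <- pixel_cluster_similarity(1, gap, D = 2, G = 3)$sim
  expect_true(all(diff(s_g) < 0))
})

test_that("similarity field is equivariant under cluster relabeling", {
  ph <- small_phantom(seed = 2)
  cs <- cluster_states(c(10, 90, 140, 220), c(20, 24, 30, 16),
                       c(22, 25, 33, 31))
  perm <- c(3, 1, 4, 2)
  f1 <- ifcmms:::similarity_field(ph$image, cs, distance = "spatial")
  f2 <- ifcmms:::similarity_field(ph$image, cs[perm, ], distance = "spatial")
  expect_equal(f1$sim[, , perm], f2$sim)
})

test_that("direct aggregation is the identity on the similarity matrix", {
  withr::with_seed(5, {
    sim <- array(runif(6 * 6 * 3, 0.1, 1), c(6, 6, 3))
    u <- ifcmms:::random_membership_stack(6, 6, 3)
    expect_identical(aggregate_sik(sim, u, mode = "direct"), sim)
  })
})

test_that("neighborhood aggregation reduces to the window mean for uniform
           memberships and to a point value for a one-hot window", {
  withr::with_seed(6, {
    sim <- array(runif(7 * 7 * 2, 0.2, 1), c(7, 7, 2))
    u_unif <- array(0.5, c(7, 7, 2))
    got <- aggregate_sik(sim, u_unif, m = 2, mode = "neighborhood")
    for (i in 1:2) {
      expect_equal(got[, , i], ifcmms:::box_mean(sim[, , i], 1),
                   tolerance = 1e-12)
    }
    # single weighted pixel in the window: S equals Sim at that pixel
    u <- array(0, c(7, 7, 2)); u[4, 4, 1] <- 1; u[, , 2] <- 1 - u[, , 1]
    got1 <- aggregate_sik(sim, u, m = 2, mode = "neighborhood")
    for (i in 4 + (-1:1)) for (j in 4 + (-1:1)) {
      expect_equal(got1[i, j, 1], sim[4, 4, 1])
    }
  })
})

test_that("zero-weight windows fall back to the direct similarity", {
  sim <- array(0.7, c(5, 5, 2))
  u <- array(0, c(5, 5, 2))  # deliberately degenerate stack
  got <- aggregate_sik(sim, u, m = 2, mode = "neighborhood")
  expect_equal(got, sim)
})
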