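test_that("DerSimonian-Laird tau2 matches the worked closed form", {
  expect_equal(dl_tau2(c(0.4, 0.4, 0.4), c(0.1, 0.2, 0.05)), 0)
  expect_equal(dl_tau2(c(0.2, 0.6), c(0.04, 0.04)), 0.04, tolerance = 1e-12)
  expect_error(dl_tau2(0.3, 0.1), "at least 2")
  expect_error(dl_tau2(c(0.1, 0.2), c(0.1, -0.1)), "positive")
  # scaling all variances: recompute through the definition as the oracle
  g <- c(0.1, 0.5, 0.9); v <- c(0.05, 0.08, 0.02); cc <- 3
  w <- 1 / (cc * v); gfe <- sum(w * g) / sum(w)
  Q <- sum(w * (g - gfe)^2); C <- sum(w) - sum(w^2) / sum(w)
  expect_equal(dl_tau2(g, cc * v), max(0, (Q - 2) / C), tolerance = 1e-12)
})

test_that("random-effects pooling reproduces the hand-computed example", {
  r <- pool_voxel(c(0.2, 0.6), c(0.04, 0.04))
  expect_equal(r$tau2, 0.04, tolerance = 1e-12)
  expect_equal(r$Q, 2.0, tolerance = 1e-12)
  expect_equal(r$pooled_effect, 0.4, tolerance = 1e-12)
  expect_equal(r$pooled_se, 0.2, tolerance = 1e-12)
  expect_equal(r$z, 2.0, tolerance = 1e-12)
  expect_equal(r$p_two_tailed, 2 * pnorm(-2), tolerance = 1e-12)
  # equal variances, no heterogeneity -> arithmetic mean
  r2 <- pool_voxel(c(0.3, 0.3), c(0.1, 0.1))
  expect_equal(r2$pooled_effect, 0.3)
  expect_error(pool_voxel(0.3, 0.1), "at least 2")
})

test_that("pooling reduces to fixed-effect weights when tau2 is zero", {
  g <- c(0.31, 0.29, 0.30); v <- c(0.05, 0.1, 0.2)
  expect_equal(dl_tau2(g, v), 0)
  r <- pool_voxel(g, v)
  w <- 1 / v
  expect_equal(r$pooled_effect, sum(w * g) / sum(w), tolerance = 1e-12)
  expect_equal(r$pooled_se, sqrt(1 / sum(w)), tolerance = 1e-12)
})

test_that("pooled SE obeys its closed-form limits", {
  # k identical studies with variance v: SE = sqrt(v/k)
  for (k in c(2, 5, 9)) {
    r <- pool_voxel(rep(0.4, k), rep(0.12, k))
    expect_equal(r$pooled_se, sqrt(0.12 / k), tolerance = 1e-12)
  }
  # pooled SE < max study SE on random instances
  set.seed(31)
  for (i in 1:25) {
    k <- sample(3:10, 1)
    g <- rnorm(k, 0, 0.6); v <- runif(k, 0.02, 0.3)
    expect_lt(pool_voxel(g, v)$pooled_se, max(sqrt(v)))
  }
})

test_that("Q is invariant to adding a constant to all effects", {
  g <- c(-0.2, 0.1, 0.9, 0.4); v <- c(0.03, 0.1, 0.06, 0.2)
  expect_equal(pool_voxel(g, v)$Q, pool_voxel(g + 5, v)$Q, tolerance = 1e-9)
})

test_that("voxel-wise pooled maps equal scalar pooling at every voxel", {
  g <- tiny_grid()
  set.seed(4)
  k <- 5; V <- length(g$mask_idx)
  G <- matrix(rnorm(k * V, 0, 0.5), k, V)
  Vm <- matrix(runif(k * V, 0.05, 0.3), k, V)
  pm <- pooled_maps(list(effects = G, variances = Vm, grid = g))
  for (j in sample(V, 8)) {
    r <- pool_voxel(G[, j], Vm[, j])
    expect_equal(pm$effect$values[j], r$pooled_effect, tolerance = 1e-10)
    expect_equal(pm$se$values[j], r$pooled_se, tolerance = 1e-10)
    expect_equal(pm$tau2$values[j], r$tau2, tolerance = 1e-10)
    expect_equal(pm$Q$values[j], r$Q, tolerance = 1e-8)
  }
  # N identical maps pool to themselves with zero heterogeneity
  G1 <- matrix(rep(G[1, ], each = 4), 4, V)
  V1 <- matrix(rep(Vm[1, ], each = 4), 4, V)
  pid <- pooled_maps(list(effects = G1, variances = V1, grid = g))
  expect_equal(pid$effect$values, G[1, ], tolerance = 1e-10)
  expect_true(all(pid$tau2$values == 0))
})

test_that("heterogeneity maps give Cochran Q with its two-study closed form", {
  g <- tiny_grid()
  V <- length(g$mask_idx)
  d1 <- rep(0.2, V); d2 <- rep(0.9, V); v <- 0.05
  qm <- q_heterogeneity_map(list(effects = rbind(d1, d2),
                                 variances = matrix(v, 2, V), grid = g))
  expect_equal(qm$Q$values, rep((0.9 - 0.2)^2 / (2 * v), V), tolerance = 1e-9)
  expect_equal(qm$p$values,
               rep(pchisq((0.7)^2 / (2 * v), 1, lower.tail = FALSE), V),
               tolerance = 1e-9)
  # identical studies: Q = 0 everywhere
  q0 <- q_heterogeneity_map(list(effects = rbind(d1, d1),
                                 variances = matrix(v, 2, V), grid = g))
  expect_true(all(abs(q0$Q$values) < 1e-10))
})

test_that("planted heterogeneity is confined to the planted locus", {
  g <- recovery_grid()
  V <- length(g$mask_idx)
  center <- c(-10, 8, 2)
  d2c <- (g$mask_mm[, 1] - center[1])^2 + (g$mask_mm[, 2] - center[2])^2 +
    (g$mask_mm[, 3] - center[3])^2
  inside <- d2c <= 100
  k <- 10
  G <- matrix(0, k, V)
  G[1:5, inside] <- 0.3; G[6:10, inside] <- 0.9
  Vm <- matrix(0.01, k, V)
  qm <- q_heterogeneity_map(list(effects = G, variances = Vm, grid = g))
  cl <- extract_clusters(qm$z, qm$p, threshold_spec(), signs = "positive")
  expect_equal(nrow(cl), 1)
  expect_true(all(cl$voxels[[1]] %in% which(inside)))
})

test_that("meta-regression matches an independent WLS oracle", {
  set.seed(77)
  for (i in 1:20) {
    k <- sample(8:18, 1)
    x <- rnorm(k, 68, 4)
    v <- runif(k, 0.05, 0.3)
    gg <- 0.02 * x + rnorm(k, 0, sqrt(v))
    r <- meta_regress_voxel(gg, v, x)
    # oracle: explicit WLS algebra with the same random-effects weights
    w <- 1 / (v + dl_tau2(gg, v))
    X <- cbind(1, x)
    beta <- solve(t(X) %*% (w * X), t(X) %*% (w * gg))
    covb <- solve(t(X) %*% (w * X))
    expect_equal(r$slope, beta[2], tolerance = 1e-10)
    expect_equal(r$slope_se, sqrt(covb[2, 2]), tolerance = 1e-10)
  }
  expect_error(meta_regress_voxel(c(0.1, 0.2), c(0.1, 0.1), c(1, 2)),
               "at least 3")
  expect_error(meta_regress_voxel(c(0.1, 0.2, 0.3), rep(0.1, 3), rep(2, 3)),
               "constant covariate")
})

test_that("meta-regression slope is recovered and unbiased in simulation", {
  set.seed(123)
  nrep <- 500; k <- 18
  slopes_link <- numeric(nrep); slopes_null <- numeric(nrep)
  for (r in seq_len(nrep)) {
    age <- rnorm(k, 68, 4)
    v <- runif(k, 0.05, 0.2)
    g_link <- 0.02 * age + rnorm(k, 0, sqrt(v))
    g_null <- 0.5 + rnorm(k, 0, sqrt(v))
    slopes_link[r] <- meta_regress_voxel(g_link, v, age)$slope
    slopes_null[r] <- meta_regress_voxel(g_null, v, age)$slope
  }
  expect_lt(abs(mean(slopes_link) - 0.02), 0.005)
  mcse <- sd(slopes_null) / sqrt(nrep)
  expect_lt(abs(mean(slopes_null)), 2 * mcse + 1e-4)
})

test_that("voxel-wise meta-regression maps agree with the scalar routine", {
  g <- tiny_grid()
  set.seed(15)
  k <- 12; V <- length(g$mask_idx)
  G <- matrix(rnorm(k * V, 0, 0.4), k, V)
  Vm <- matrix(runif(k * V, 0.05, 0.2), k, V)
  x <- c(rnorm(k - 2, 68, 4), NA, NA)
  mr <- meta_regress_maps(list(effects = G, variances = Vm, grid = g), x)
  expect_equal(mr$n_studies_used, k - 2)
  for (j in sample(V, 6)) {
    r <- meta_regress_voxel(G[, j], Vm[, j], x)
    expect_equal(mr$slope$values[j], r$slope, tolerance = 1e-9)
    expect_equal(mr$z$values[j], r$z, tolerance = 1e-9)
  }
})
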