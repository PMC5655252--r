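# build z/p volume maps with chosen z values at chosen in-mask positions
make_maps <- function(g, zvals) {
  z <- volume_map(g, zvals, "z")
  p <- volume_map(g, pmax(2 * pnorm(-abs(zvals)), .Machine$double.xmin), "p")
  list(z = z, p = p)
}

cluster_df_public <- function(fit) {
  d <- as.data.frame(fit$clusters)
  d$voxels <- lapply(d$voxels, sort)
  d
}

# positions (mask order) of a straight run of voxels along x at y=z=0
line_positions <- function(g, n, from = -20) {
  mm <- cbind(seq(from, by = g$voxel_mm, length.out = n), 0, 0)
  match(mm_to_voxel(g, mm), g$mask_idx)
}

test_that("cluster extraction finds blobs and honours the extent rule", {
  g <- tiny_grid()
  V <- length(g$mask_idx)
  zv <- rep(0, V)
  pos12 <- line_positions(g, 12)  # x from -20 to 24, inside the box
  zv[pos12] <- -c(3, 3.5, 4, 4.5, 5, 4.5, 4, 3.5, 3, 3, 3, 3)
  m <- make_maps(g, zv)
  cl <- extract_clusters(m$z, m$p)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$extent, 12)
  expect_equal(cl$sign, "reduction")
  expect_equal(cl$peak_zstat, -5)
  expect_equal(sort(cl$voxels[[1]]), sort(pos12))
  # 9 suprathreshold voxels fall below the 10-voxel extent default
  zv9 <- rep(0, V); zv9[line_positions(g, 9)] <- -4
  m9 <- make_maps(g, zv9)
  expect_equal(nrow(extract_clusters(m9$z, m9$p)), 0)
  # an all-null map yields an empty table
  mn <- make_maps(g, rep(0, V))
  expect_equal(nrow(extract_clusters(mn$z, mn$p)), 0)
})

test_that("negative and positive signs form separate clusters", {
  g <- tiny_grid()
  V <- length(g$mask_idx)
  zv <- rep(0, V)
  neg <- line_positions(g, 11, from = -32)
  posi <- match(mm_to_voxel(g, cbind(seq(-20, by = 4, length.out = 11), 16, 0)),
                g$mask_idx)
  zv[neg] <- -4; zv[posi] <- 4
  m <- make_maps(g, zv)
  cl <- extract_clusters(m$z, m$p)
  expect_equal(sort(cl$sign), c("increase", "reduction"))
  cln <- extract_clusters(m$z, m$p, signs = "negative")
  expect_equal(cln$sign, "reduction")
})

test_that("raising the extent threshold never increases the cluster count", {
  g <- recovery_grid()
  set.seed(21)
  ds <- simulate_dataset(truth_spec(clusters = list(
    list(center = c(-10, 8, 2), radius_mm = 10, g = -0.8)), seed = 21), g)
  fit <- sdm_meta(ds$studies, ds$peaks, grid = g)
  counts <- sapply(c(5, 10, 50, 500), function(ext)
    nrow(extract_clusters(fit$pooled$z, fit$pooled$p,
                          threshold_spec(min_extent_voxels = ext))))
  expect_true(all(diff(counts) <= 0))
})

test_that("cluster peak ties break at the smallest linear index", {
  g <- tiny_grid()
  V <- length(g$mask_idx)
  zv <- rep(0, V)
  pos <- line_positions(g, 12)
  zv[pos] <- -4            # all tied
  m <- make_maps(g, zv)
  cl <- extract_clusters(m$z, m$p)
  expect_equal(mask_pos_of_peak(g, cl[1, ]), min(pos))
})

test_that("jackknife replicates N out of N on identical strong studies", {
  g <- tiny_grid()
  V <- length(g$mask_idx)
  center <- c(0, 0, 0)
  d2c <- (g$mask_mm[, 1])^2 + (g$mask_mm[, 2])^2 + (g$mask_mm[, 3])^2
  eff <- ifelse(d2c <= 12^2, -1.2, 0)
  k <- 6
  maps <- list(effects = matrix(rep(eff, each = k), k, V),
               variances = matrix(0.05, k, V), grid = g)
  pm <- pooled_maps(maps)
  cl <- extract_clusters(pm$z, pm$p)
  expect_equal(nrow(cl), 1)
  jk <- jackknife(maps, cl)
  expect_equal(dim(jk$table), c(k, 1))
  expect_equal(unname(jk$replication), k)
  expect_true(all(jk$replication <= jk$n))
})

test_that("a cluster carried by one strong study drops out when it is omitted", {
  g <- tiny_grid()
  V <- length(g$mask_idx)
  blob <- rowSums(g$mask_mm^2) <= 12^2
  # two weak studies (not significant alone) plus one strong carrier
  k <- 3
  G <- rbind(ifelse(blob, -0.4, 0), ifelse(blob, -0.4, 0),
             ifelse(blob, -0.8, 0))
  Vm <- rbind(matrix(0.1, 2, V), matrix(0.02, 1, V))
  maps <- list(effects = G, variances = Vm, grid = g)
  pm <- pooled_maps(maps)
  cl <- extract_clusters(pm$z, pm$p)
  expect_gte(nrow(cl), 1)
  jk <- jackknife(maps, cl)
  expect_false(jk$table[k, 1])          # omitting the carrier loses the cluster
  expect_lt(jk$replication[1], jk$n)
})

test_that("Egger regression matches a textbook WLS/OLS oracle", {
  g4 <- c(0.8, 0.5, 0.35, 0.2)
  s4 <- c(0.45, 0.3, 0.2, 0.1)
  r <- egger_test(g4, s4)
  o <- summary(lm(I(g4 / s4) ~ I(1 / s4)))$coefficients
  expect_equal(r$intercept, o[1, 1], tolerance = 1e-10)
  expect_equal(r$intercept_se, o[1, 2], tolerance = 1e-10)
  expect_equal(r$t, o[1, 3], tolerance = 1e-10)
  expect_equal(r$p, o[1, 4], tolerance = 1e-10)
  expect_equal(r$n_studies, 4)
  # identical studies: one funnel point, no asymmetry
  r0 <- egger_test(rep(0.5, 5), rep(0.2, 5))
  expect_equal(r0$intercept, 0)
  expect_equal(r0$p, 1)
  # fewer than 3 usable studies is flagged not computable
  expect_false(egger_test(c(0.1, 0.2), c(0.1, 0.1))$computable)
})

test_that("Egger at peaks extracts per-study values at the cluster peak", {
  g <- tiny_grid()
  V <- length(g$mask_idx)
  d2c <- rowSums(g$mask_mm^2)
  k <- 4
  amp <- c(-1.4, -1.0, -0.8, -0.6)
  G <- t(sapply(amp, function(a) ifelse(d2c <= 12^2, a, 0)))
  Vm <- matrix(rep(c(0.2, 0.12, 0.08, 0.05), V), k, V)
  maps <- list(effects = G, variances = Vm, grid = g)
  pm <- pooled_maps(maps)
  cl <- extract_clusters(pm$z, pm$p)
  res <- egger_at_peaks(maps, cl[1, ])
  pkv <- mask_pos_of_peak(g, cl[1, ])
  oracle <- egger_test(G[, pkv], sqrt(Vm[, pkv]))
  expect_equal(res$intercept[1], oracle$intercept, tolerance = 1e-10)
  f <- attr(res, "funnel")[[1]]
  expect_equal(f$g, G[, pkv])
  expect_equal(f$precision, 1 / sqrt(Vm[, pkv]))
})

test_that("cluster extraction is invariant to study order upstream", {
  g <- recovery_grid()
  ds <- simulate_dataset(truth_spec(clusters = list(
    list(center = c(8, -6, 4), radius_mm = 10, g = -0.8)), seed = 33), g)
  fit1 <- sdm_meta(ds$studies, ds$peaks, grid = g)
  perm <- rev(seq_len(nrow(ds$studies)))
  studies2 <- ds$studies[perm, ]; class(studies2) <- class(ds$studies)
  peaks2 <- ds$peaks[perm]; class(peaks2) <- "peak_tables"
  fit2 <- sdm_meta(studies2, peaks2, grid = g)
  expect_equal(cluster_df_public(fit1), cluster_df_public(fit2))
})
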