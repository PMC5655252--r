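#' DerSimonian-Laird between-study variance
#'
#' Moment estimator of the between-study heterogeneity tau^2:
#' `tau2 = max(0, (Q - (k-1)) / C)` with fixed-effect weights `w = 1/v`,
#' `Q = sum w (g - g_FE)^2` and `C = sum w - sum w^2 / sum w`.
#'
#' @param effects vector of study effect sizes (length k >= 2).
#' @param variances vector of their sampling variances (> 0).
#' @return nonnegative tau^2.
#' @examples
#' dl_tau2(c(0.2, 0.6), c(0.04, 0.04))  # 0.04
#' @export
dl_tau2 <- function(effects, variances) {
  k <- length(effects)
  if (k < 2L) stop("at least 2 studies are required")
  if (any(variances <= 0)) stop("variances must be strictly positive")
  w <- 1 / variances
  gfe <- sum(w * effects) / sum(w)
  Q <- sum(w * (effects - gfe)^2)
  C <- sum(w) - sum(w^2) / sum(w)
  max(0, (Q - (k - 1)) / C)
}

#' Random-effects pooling at one voxel
#'
#' Pools study effect sizes with DerSimonian-Laird random-effects weights
#' `w* = 1/(v + tau2)`. Sample size enters through the sampling variances
#' (see [g_variance()]), so the pooled mean is weighted by sample size,
#' within-study variability and between-study heterogeneity.
#'
#' @param effects,variances study effect sizes and variances (length k >= 2).
#' @return list with `pooled_effect`, `pooled_se`, `tau2`, `Q`, `z`,
#'   `p_two_tailed`.
#' @examples
#' pool_voxel(c(0.2, 0.6), c(0.04, 0.04))
#' @export
pool_voxel <- function(effects, variances) {
  tau2 <- dl_tau2(effects, variances)
  w <- 1 / (variances + tau2)
  if (all(w == 0)) stop("all pooling weights are zero")
  pooled <- sum(w * effects) / sum(w)
  se <- sqrt(1 / sum(w))
  z <- pooled / se
  wfe <- 1 / variances
  gfe <- sum(wfe * effects) / sum(wfe)
  list(pooled_effect = pooled, pooled_se = se, tau2 = tau2,
       Q = sum(wfe * (effects - gfe)^2), z = z,
       p_two_tailed = 2 * stats::pnorm(-abs(z)))
}

# vectorized pooling over a k x V effect/variance matrix pair
pool_matrix <- function(G, Vm) {
  k <- nrow(G)
  if (k < 2L) stop("at least 2 studies are required")
  W <- 1 / Vm
  sw <- colSums(W)
  gfe <- colSums(W * G) / sw
  Q <- colSums(W * G^2) - sw * gfe^2
  Q <- pmax(Q, 0)                                   # guard tiny negatives
  C <- sw - colSums(W^2) / sw
  tau2 <- pmax(0, (Q - (k - 1)) / C)
  Ws <- 1 / sweep(Vm, 2, tau2, "+")
  sws <- colSums(Ws)
  pooled <- colSums(Ws * G) / sws
  se <- sqrt(1 / sws)
  z <- pooled / se
  list(pooled = pooled, se = se, tau2 = tau2, Q = Q, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Voxel-wise random-effects mean maps
#'
#' Applies [pool_voxel()] independently at every in-mask voxel of a set of
#' reconstructed study maps.
#'
#' @param maps output of [reconstruct_all_studies()] (matrices `effects`,
#'   `variances` and the shared `grid`), or a list of per-study
#'   `list(effect=, variance=)` [volume_map()] pairs on one grid.
#' @return list of [volume_map()]s: `effect`, `se`, `z`, `p`, `Q`, `tau2`.
#' @export
pooled_maps <- function(maps) {
  mm <- as_map_matrices(maps)
  r <- pool_matrix(mm$effects, mm$variances)
  g <- mm$grid
  list(effect = volume_map(g, r$pooled, "d"),
       se = volume_map(g, r$se, "v"),
       z = volume_map(g, r$z, "z"),
       p = volume_map(g, pmax(r$p, .Machine$double.xmin), "p"),
       Q = volume_map(g, r$Q, "q"),
       tau2 = volume_map(g, r$tau2, "q"))
}

as_map_matrices <- function(maps) {
  if (!is.null(maps$effects)) {
    stopifnot(identical(dim(maps$effects), dim(maps$variances)))
    return(maps)
  }
  grids <- lapply(maps, function(m) m$effect$grid)
  for (g in grids[-1]) if (!same_grid(grids[[1]], g)) stop("grid mismatch across study maps")
  list(effects = do.call(rbind, lapply(maps, function(m) m$effect$values)),
       variances = do.call(rbind, lapply(maps, function(m) m$variance$values)),
       grid = grids[[1]])
}

#' Voxel-wise Cochran Q heterogeneity map
#'
#' Cochran's Q with fixed-effect weights at every in-mask voxel, and its
#' chi-square p value on k-1 degrees of freedom. Large Q marks voxels where
#' the studies disagree beyond sampling error.
#'
#' @inheritParams pooled_maps
#' @return list of [volume_map()]s `Q` and `p` (and `z`, the signed normal
#'   quantile of the chi-square p used for cluster thresholding).
#' @export
q_heterogeneity_map <- function(maps) {
  mm <- as_map_matrices(maps)
  k <- nrow(mm$effects)
  r <- pool_matrix(mm$effects, mm$variances)
  p <- stats::pchisq(r$Q, df = k - 1, lower.tail = FALSE)
  p <- pmax(p, .Machine$double.xmin)
  z <- stats::qnorm(p, lower.tail = FALSE)
  list(Q = volume_map(mm$grid, r$Q, "q"),
       p = volume_map(mm$grid, p, "p"),
       z = volume_map(mm$grid, pmin(pmax(z, 0), 40), "z"))
}

#' Random-effects meta-regression at one voxel
#'
#' Weighted least squares of study effect sizes on an intercept and one
#' covariate with random-effects weights `1/(v + tau2)` (tau2 from the
#' DerSimonian-Laird estimator on the residual-free model). Studies with a
#' missing covariate are dropped and counted.
#'
#' @param effects,variances study effect sizes and sampling variances.
#' @param covariate study-level covariate, may contain `NA`.
#' @return list with `slope`, `slope_se`, `z`, `p`, `n_studies_used`,
#'   `intercept`.
#' @export
meta_regress_voxel <- function(effects, variances, covariate) {
  keep <- !is.na(covariate)
  effects <- effects[keep]; variances <- variances[keep]
  x <- covariate[keep]
  k <- length(effects)
  if (k < 3L) stop("at least 3 studies with the covariate are required")
  if (stats::sd(x) == 0) stop("constant covariate: singular design")
  tau2 <- dl_tau2(effects, variances)
  w <- 1 / (variances + tau2)
  X <- cbind(1, x)
  XtW <- t(X * w)
  beta <- solve(XtW %*% X, XtW %*% effects)
  covb <- solve(XtW %*% X)
  se <- sqrt(covb[2, 2])
  z <- beta[2] / se
  list(slope = beta[2], slope_se = se, z = z,
       p = 2 * stats::pnorm(-abs(z)), n_studies_used = k,
       intercept = beta[1])
}

#' Voxel-wise meta-regression maps
#'
#' [meta_regress_voxel()] applied at every in-mask voxel, vectorized. Returns
#' slope, z and p maps for the covariate effect.
#'
#' @inheritParams pooled_maps
#' @param covariate study-level covariate vector (one per study, `NA`
#'   allowed — those studies are dropped).
#' @return list of [volume_map()]s `slope`, `z`, `p`, plus
#'   `n_studies_used`.
#' @export
meta_regress_maps <- function(maps, covariate) {
  mm <- as_map_matrices(maps)
  keep <- !is.na(covariate)
  G <- mm$effects[keep, , drop = FALSE]
  Vm <- mm$variances[keep, , drop = FALSE]
  x <- covariate[keep]
  k <- nrow(G)
  if (k < 3L) stop("at least 3 studies with the covariate are required")
  if (stats::sd(x) == 0) stop("constant covariate: singular design")
  # voxel-wise DL tau2, then WLS with weights 1/(v+tau2)
  r <- pool_matrix(G, Vm)
  W <- 1 / sweep(Vm, 2, r$tau2, "+")
  sw <- colSums(W)
  sx <- colSums(W * x)
  sxx <- colSums(W * x^2)
  sy <- colSums(W * G)
  sxy <- colSums(W * x * G)
  det <- sw * sxx - sx^2
  slope <- (sw * sxy - sx * sy) / det
  se <- sqrt(sw / det)
  z <- slope / se
  p <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  list(slope = volume_map(mm$grid, slope, "d"),
       z = volume_map(mm$grid, z, "z"),
       p = volume_map(mm$grid, p, "p"),
       n_studies_used = k)
}
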