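#' Un-normalised Gaussian proximity kernel
#'
#' The kernel assigns each voxel an indicator of proximity to a reported
#' peak: `w(d) = exp(-4 * ln 2 * d^2 / FWHM^2)`, so the weight is 1 at the
#' peak and 0.5 at half the FWHM. It is not a smoothing kernel — it does not
#' integrate to one — and it is truncated to exactly 0 beyond
#' `truncation_radius_mm` (default 30 mm, where the weight has fallen below
#' 0.002 at the default 20 mm FWHM).
#'
#' @param fwhm_mm full width at half maximum in mm (default 20).
#' @param truncation_radius_mm hard cutoff radius, at least `fwhm_mm`.
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(fwhm_mm = 20, truncation_radius_mm = 30) {
  stopifnot(fwhm_mm > 0, truncation_radius_mm >= fwhm_mm)
  structure(list(fwhm_mm = fwhm_mm, truncation_radius_mm = truncation_radius_mm),
            class = "kernel_spec")
}

#' @rdname kernel_spec
#' @param distance_mm nonnegative distances in mm.
#' @param spec a `kernel_spec`.
#' @return weights in `[0, 1]`.
#' @examples
#' kernel_weight(10, kernel_spec(fwhm_mm = 20))  # exactly 0.5
#' @export
kernel_weight <- function(distance_mm, spec = kernel_spec()) {
  if (any(distance_mm < 0)) stop("distances must be nonnegative")
  w <- exp(-4 * log(2) * distance_mm^2 / spec$fwhm_mm^2)
  w[distance_mm > spec$truncation_radius_mm] <- 0
  w
}

#' Reconstruct a study's effect-size and variance maps from its peaks
#'
#' Recreates the signed effect-size map a study would have shown near its
#' reported peaks: each in-mask voxel receives the kernel-weighted mean of
#' the effect sizes of all peaks within the truncation radius (weights from
#' [kernel_weight()]), and 0 where no peak contributes. Because the value is
#' a convex combination, its magnitude never exceeds the largest
#' contributing peak magnitude. The variance map applies [g_variance()] to
#' the reconstructed value with the study's group sizes; voxels with value 0
#' get the floor `g_variance(0, n1, n2)` so random-effects weights are
#' defined everywhere.
#'
#' Peaks falling outside the analysis mask are snapped to the nearest
#' in-mask voxel with a warning.
#'
#' @param peaks data.frame with columns `x`, `y`, `z` (MNI mm) and `g`
#'   (signed effect size) — one study's prepared peaks (see
#'   [prepare_peaks()]).
#' @param n1,n2 the study's group sizes.
#' @param grid a [brain_grid()].
#' @param kernel a [kernel_spec()].
#' @return list with `effect` and `variance` [volume_map()]s plus `weight`,
#'   the per-voxel total kernel weight (contribution bookkeeping).
#' @export
reconstruct_study_maps <- function(peaks, n1, n2, grid, kernel = kernel_spec()) {
  V <- length(grid$mask_idx)
  num <- numeric(V); den <- numeric(V)
  if (nrow(peaks)) {
    xyz <- as.matrix(peaks[, c("x", "y", "z")])
    # snap out-of-mask peaks to the nearest in-mask voxel
    for (i in seq_len(nrow(xyz))) {
      li <- mm_to_voxel(grid, xyz[i, ])
      if (!grid$mask[li]) {
        d2 <- (grid$mask_mm[, 1] - xyz[i, 1])^2 +
              (grid$mask_mm[, 2] - xyz[i, 2])^2 +
              (grid$mask_mm[, 3] - xyz[i, 3])^2
        j <- which.min(d2)
        warning(sprintf("peak (%g, %g, %g) outside mask; snapped to nearest in-mask voxel (%g, %g, %g)",
                        xyz[i, 1], xyz[i, 2], xyz[i, 3],
                        grid$mask_mm[j, 1], grid$mask_mm[j, 2], grid$mask_mm[j, 3]))
        xyz[i, ] <- grid$mask_mm[j, ]
      }
    }
    for (i in seq_len(nrow(xyz))) {
      d <- sqrt((grid$mask_mm[, 1] - xyz[i, 1])^2 +
                (grid$mask_mm[, 2] - xyz[i, 2])^2 +
                (grid$mask_mm[, 3] - xyz[i, 3])^2)
      near <- which(d <= kernel$truncation_radius_mm)
      if (!length(near)) next
      w <- kernel_weight(d[near], kernel)
      num[near] <- num[near] + w * peaks$g[i]
      den[near] <- den[near] + w
    }
  }
  eff <- ifelse(den > 0, num / den, 0)
  v <- g_variance(eff, n1, n2)
  list(effect = volume_map(grid, eff, "d"),
       variance = volume_map(grid, v, "v"),
       weight = den)
}

#' Reconstruct all studies' maps as matrices
#'
#' Convenience wrapper producing the k-by-V effect and variance matrices the
#' pooling step consumes (k studies by V in-mask voxels).
#'
#' @param peaks a `peak_tables` list (raw, any coordinate space).
#' @param studies the matching `study_table`.
#' @param grid a [brain_grid()].
#' @param kernel a [kernel_spec()].
#' @return list with matrices `effects`, `variances` (rows = studies) and
#'   the `grid`.
#' @export
reconstruct_all_studies <- function(peaks, studies, grid, kernel = kernel_spec()) {
  prepped <- prepare_peaks(peaks, studies)
  k <- nrow(studies); V <- length(grid$mask_idx)
  G <- matrix(0, k, V, dimnames = list(studies$study_id, NULL))
  W <- matrix(0, k, V, dimnames = list(studies$study_id, NULL))
  for (i in seq_len(k)) {
    m <- reconstruct_study_maps(prepped[[i]], studies$n_patients[i],
                                studies$n_controls[i], grid, kernel)
    G[i, ] <- m$effect$values
    W[i, ] <- m$variance$values
  }
  list(effects = G, variances = W, grid = grid)
}
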