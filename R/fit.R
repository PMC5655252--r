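#' Fit a coordinate-based meta-analysis
#'
#' The central fitting function: reconstructs each study's signed
#' effect-size and variance maps from its reported peaks (un-normalised
#' Gaussian proximity kernel), pools them voxel-wise with a
#' DerSimonian-Laird random-effects model, and extracts suprathreshold
#' clusters of gray-matter reduction and increase separately.
#'
#' @param studies a `study_table` (see [load_study_table()]).
#' @param peaks a `peak_tables` list (see [load_peak_tables()]).
#' @param grid a [brain_grid()]; default 2 mm MNI grid with the coarse
#'   gray-matter ellipsoid mask.
#' @param kernel a [kernel_spec()] (default FWHM 20 mm, truncation 30 mm).
#' @param threshold a [threshold_spec()] (default p < 0.005, peak |Z| >= 1,
#'   extent >= 10 voxels).
#' @param subset optional logical or integer index restricting the studies
#'   (used by [run_subgroup()]).
#' @return object of class `sdm_meta` with elements `studies`, `maps`
#'   (per-study effect/variance matrices), `pooled` (effect, se, z, p, Q,
#'   tau2 [volume_map()]s), `clusters` (all signs), `reductions`,
#'   `increases`, and the specs used.
#' @examples
#' g <- brain_grid(voxel_mm = 4, bbox = cbind(c(-40, -40, -40), c(40, 40, 40)))
#' ds <- simulate_dataset(truth_spec(k_studies = 6, seed = 3), g)
#' fit <- sdm_meta(ds$studies, ds$peaks, grid = g)
#' fit
#' @export
sdm_meta <- function(studies, peaks, grid = brain_grid(),
                     kernel = kernel_spec(), threshold = threshold_spec(),
                     subset = NULL) {
  if (!is.null(subset)) {
    studies <- studies[subset, , drop = FALSE]
    class(studies) <- c("study_table", "data.frame")
    peaks <- split_peaks(do.call(rbind, c(unname(peaks), list(empty_peak_df()))),
                         studies)
  }
  if (nrow(studies) < 2L) stop("at least 2 studies are required")
  maps <- reconstruct_all_studies(peaks, studies, grid, kernel)
  pooled <- pooled_maps(maps)
  clusters <- extract_clusters(pooled$z, pooled$p, threshold)
  structure(list(studies = studies, maps = maps, pooled = pooled,
                 clusters = clusters,
                 reductions = clusters[clusters$sign == "reduction", ],
                 increases = clusters[clusters$sign == "increase", ],
                 grid = grid, kernel = kernel, threshold = threshold,
                 call = match.call()),
            class = "sdm_meta")
}

#' @export
print.sdm_meta <- function(x, ...) {
  cat("Coordinate-based meta-analysis (random-effects effect-size mapping)\n")
  cat(sprintf("  %d studies, %d patients, %d controls; %d in-mask voxels\n",
              nrow(x$studies), sum(x$studies$n_patients),
              sum(x$studies$n_controls), length(x$grid$mask_idx)))
  cat(sprintf("  kernel FWHM %g mm; voxel p < %g, peak |Z| >= %g, extent >= %d\n",
              x$kernel$fwhm_mm, x$threshold$p_voxel,
              x$threshold$min_peak_abs_z, x$threshold$min_extent_voxels))
  cat(sprintf("  clusters: %d reduction, %d increase\n",
              nrow(x$reductions), nrow(x$increases)))
  invisible(x)
}

#' @export
summary.sdm_meta <- function(object, ...) {
  cat("Gray-matter reductions (patients vs controls):\n")
  print(cluster_df(object$reductions))
  cat("\nGray-matter increases (patients vs controls):\n")
  print(cluster_df(object$increases))
  invisible(object)
}

cluster_df <- function(cl) {
  d <- as.data.frame(cl)[, c("peak_x", "peak_y", "peak_z", "extent",
                             "peak_zstat", "peak_p"), drop = FALSE]
  names(d) <- c("x", "y", "z", "n_voxels", "SDM_Z", "p")
  d
}

#' @export
coef.sdm_meta <- function(object, ...) {
  cl <- object$clusters
  if (!nrow(cl)) return(numeric())
  vapply(seq_len(nrow(cl)), function(j) {
    object$pooled$effect$values[mask_pos_of_peak(object$grid, cl[j, ])]
  }, numeric(1))
}

#' Funnel plot of a fitted meta-analysis cluster
#'
#' Plots per-study effect size against precision at a cluster's peak voxel.
#' @param x an `sdm_meta` fit.
#' @param cluster which cluster row to plot (default 1).
#' @param ... passed to [graphics::plot()].
#' @export
plot.sdm_meta <- function(x, cluster = 1, ...) {
  if (!nrow(x$clusters)) stop("no clusters to plot")
  eg <- egger_at_peaks(x$maps, x$clusters[cluster, , drop = FALSE])
  f <- attr(eg, "funnel")[[1]]
  graphics::plot(f$g, f$precision, xlab = "effect size g",
                 ylab = "precision 1/SE",
                 main = sprintf("Funnel plot, cluster %d (Egger p = %.3f)",
                                cluster, eg$p[1]), ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Jackknife sensitivity analysis of a fitted meta-analysis
#'
#' @param fit an `sdm_meta` fit.
#' @return see [jackknife()].
#' @export
sdm_jackknife <- function(fit) {
  jackknife(fit$maps, fit$clusters, fit$threshold)
}

#' Heterogeneity analysis of a fitted meta-analysis
#'
#' Voxel-wise Cochran Q with cluster extraction at the same default
#' thresholds as the main analysis.
#' @param fit an `sdm_meta` fit.
#' @return list with the `Q`/`p`/`z` maps and `clusters` of significant
#'   heterogeneity.
#' @export
sdm_heterogeneity <- function(fit) {
  qm <- q_heterogeneity_map(fit$maps)
  clusters <- extract_clusters(qm$z, qm$p, fit$threshold, signs = "positive")
  list(Q = qm$Q, p = qm$p, z = qm$z, clusters = clusters)
}

#' Publication-bias (Egger) tests at the fitted meta-analytic peaks
#'
#' @param fit an `sdm_meta` fit.
#' @param alpha significance level for flagging asymmetry (default 0.05).
#' @return the [egger_at_peaks()] table with a `significant` column.
#' @export
sdm_egger <- function(fit, alpha = 0.05) {
  if (!nrow(fit$clusters)) stop("no clusters: nothing to test")
  res <- egger_at_peaks(fit$maps, fit$clusters)
  res$significant <- res$p < alpha
  res
}

#' Voxel-wise meta-regressions over study covariates
#'
#' Runs [meta_regress_maps()] for each requested study-level covariate,
#' enforcing the availability rule: a covariate reported by fewer than
#' `min_covariate_studies` studies is skipped with a logged reason. Maps
#' are thresholded at the conservative meta-regression defaults
#' (p < 0.0005, extent > 10 voxels).
#'
#' @param fit an `sdm_meta` fit.
#' @param covariates named list mapping a covariate label to the vector of
#'   study-level values (or a character vector of study-table column
#'   names).
#' @param min_covariate_studies availability rule (default 10).
#' @param threshold a [threshold_spec()] for the regression maps.
#' @return list with one entry per covariate: either
#'   `list(skipped = TRUE, reason = ...)` or `list(skipped = FALSE, maps,
#'   clusters, n_studies_used)`.
#' @export
sdm_metaregression <- function(fit, covariates,
                               min_covariate_studies = 10,
                               threshold = threshold_spec(p_voxel = 5e-4,
                                                          min_extent_voxels = 11)) {
  if (is.character(covariates)) {
    nm <- covariates
    covariates <- lapply(nm, function(cv) fit$studies[[cv]])
    names(covariates) <- nm
  }
  out <- lapply(names(covariates), function(nm) {
    x <- covariates[[nm]]
    n_avail <- sum(!is.na(x))
    if (n_avail < min_covariate_studies) {
      return(list(skipped = TRUE, n_available = n_avail,
                  reason = sprintf("covariate '%s' available in %d < %d studies",
                                   nm, n_avail, min_covariate_studies)))
    }
    mr <- meta_regress_maps(fit$maps, x)
    clusters <- extract_clusters(mr$z, mr$p, threshold)
    list(skipped = FALSE, n_available = n_avail, maps = mr,
         clusters = clusters, n_studies_used = mr$n_studies_used)
  })
  names(out) <- names(covariates)
  out
}

#' Refit the meta-analysis on a tagged study subgroup
#'
#' @param studies,peaks the full dataset.
#' @param tag subgroup tag to keep (matched against the semicolon-free
#'   `subgroup_tags` column).
#' @param ... passed to [sdm_meta()].
#' @return an `sdm_meta` fit on the subgroup, with `subgroup_tag` and
#'   `subgroup_size` recorded.
#' @export
run_subgroup <- function(studies, peaks, tag, ...) {
  keep <- !is.na(studies$subgroup_tags) &
    vapply(strsplit(studies$subgroup_tags, ";"),
           function(tags) tag %in% tags, logical(1))
  if (sum(keep) < 2L) stop("fewer than 2 studies carry tag '", tag, "'")
  fit <- sdm_meta(studies, peaks, subset = keep, ...)
  fit$subgroup_tag <- tag
  fit$subgroup_size <- sum(keep)
  fit
}
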