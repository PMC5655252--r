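#' Ground-truth specification for synthetic coordinate datasets
#'
#' Describes the data-generating process the synthetic module emulates: a
#' set of true atrophy/hypertrophy loci (spheres with a signed effect size),
#' the number of studies, per-group sample-size range, true between-study
#' heterogeneity, and the per-study voxel threshold at which each simulated
#' study "publishes" its peaks.
#'
#' Defaults mirror the study pool the packaged fixture describes: 18
#' studies with 10-24 subjects per group, per-study thresholds of
#' p < 0.001, and a single gray-matter reduction locus of magnitude 0.8.
#'
#' @param clusters list of `list(center = c(x,y,z) mm, radius_mm, g)`.
#' @param k_studies number of studies (>= 2).
#' @param n_range integer pair: min/max per-group sample size.
#' @param tau2_true true between-study variance of the planted effect.
#' @param study_threshold_p per-study two-tailed voxel threshold.
#' @param covariate_links optional named list (e.g. `list(age_patient_mean
#'   = 0.02)`) adding `slope * (x_i - mean(x))` to each study's planted
#'   effect amplitude, for meta-regression recovery experiments.
#' @param seed integer seed recorded in, and used by, [simulate_dataset()].
#' @return object of class `truth_spec`.
#' @export
truth_spec <- function(clusters = list(list(center = c(-42, 14, 2),
                                            radius_mm = 10, g = -0.8)),
                       k_studies = 18, n_range = c(10, 24), tau2_true = 0,
                       study_threshold_p = 0.001, covariate_links = NULL,
                       seed = 1L) {
  stopifnot(k_studies >= 2, tau2_true >= 0,
            study_threshold_p > 0, study_threshold_p < 1,
            n_range[1] >= 2, n_range[2] >= n_range[1])
  for (cl in clusters)
    stopifnot(length(cl$center) == 3, cl$radius_mm > 0, is.numeric(cl$g))
  structure(list(clusters = clusters, k_studies = as.integer(k_studies),
                 n_range = as.integer(n_range), tau2_true = tau2_true,
                 study_threshold_p = study_threshold_p,
                 covariate_links = covariate_links, seed = as.integer(seed)),
            class = "truth_spec")
}

# true effect field over the in-mask voxels: g inside spheres, 0 outside
true_effect_field <- function(truth, grid) {
  f <- numeric(length(grid$mask_idx))
  for (cl in truth$clusters) {
    d2 <- (grid$mask_mm[, 1] - cl$center[1])^2 +
          (grid$mask_mm[, 2] - cl$center[2])^2 +
          (grid$mask_mm[, 3] - cl$center[3])^2
    inside <- d2 <= cl$radius_mm^2
    f[inside] <- cl$g
  }
  f
}

# local maxima of |d| among suprathreshold voxels (26-neighborhood),
# mirroring the cluster-peak conventions of the inference step
local_maxima <- function(abs_d_array, supra_lin, shape) {
  if (!length(supra_lin)) return(integer())
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  ijk <- arrayInd(supra_lin, shape)
  keep <- logical(length(supra_lin))
  for (s in seq_along(supra_lin)) {
    v <- abs_d_array[supra_lin[s]]
    is_max <- TRUE
    for (o in seq_len(nrow(off))) {
      q <- ijk[s, ] + off[o, ]
      if (q[1] < 1 || q[1] > nx || q[2] < 1 || q[2] > ny ||
          q[3] < 1 || q[3] > nz) next
      if (abs_d_array[q[1] + nx * ((q[2] - 1) + ny * (q[3] - 1))] >= v) {
        is_max <- FALSE; break
      }
    }
    keep[s] <- is_max
  }
  supra_lin[keep]
}

#' Simulate one study's metadata and reported peaks
#'
#' Draws group sizes and demographics, builds the study's true effect field
#' (planted spheres plus a study-level heterogeneity offset inside them,
#' plus any covariate link), adds independent voxel noise with the sampling
#' variance implied by [g_variance()], thresholds the resulting t field at
#' the study's threshold, and reports the surviving local maxima as the
#' study's peak table — the same winner's-curse reporting real studies
#' apply.
#'
#' Randomness comes from the current RNG state; callers (normally
#' [simulate_dataset()]) are responsible for seeding.
#'
#' @param truth a [truth_spec()].
#' @param grid a [brain_grid()].
#' @param study_index integer used for the study id.
#' @return list with `study` (one-row data.frame in the study-table schema)
#'   and `peaks` (data.frame in the peak-table schema).
#' @export
simulate_study <- function(truth, grid, study_index = 1L) {
  if (!length(grid$mask_idx)) stop("empty mask")
  n1 <- sample(truth$n_range[1]:truth$n_range[2], 1)
  n2 <- sample(truth$n_range[1]:truth$n_range[2], 1)
  covs <- list(age_patient_mean = stats::rnorm(1, 68, 3),
               updrs3_mean = stats::rnorm(1, 33, 8),
               mmse_mean = stats::rnorm(1, 25, 2),
               duration_mean = stats::rnorm(1, 3.5, 0.8))
  male_p <- stats::rbinom(1, n1, 0.6)
  male_c <- stats::rbinom(1, n2, 0.55)

  amp_shift <- 0
  if (!is.null(truth$covariate_links)) {
    mu <- c(age_patient_mean = 68, updrs3_mean = 33, mmse_mean = 25,
            duration_mean = 3.5)
    for (nm in names(truth$covariate_links))
      amp_shift <- amp_shift +
        truth$covariate_links[[nm]] * (covs[[nm]] - mu[[nm]])
  }
  offset <- if (truth$tau2_true > 0) stats::rnorm(1, 0, sqrt(truth$tau2_true)) else 0

  d_true <- true_effect_field(truth, grid)
  in_cluster <- d_true != 0
  d_true[in_cluster] <- d_true[in_cluster] + offset + amp_shift
  noise_sd <- sqrt(g_variance(d_true, n1, n2))
  d_obs <- d_true + stats::rnorm(length(d_true), 0, noise_sd)

  scale <- j_correction(n1, n2) * sqrt(1 / n1 + 1 / n2)
  t_obs <- d_obs / scale
  t_crit <- stats::qt(1 - truth$study_threshold_p / 2, df = n1 + n2 - 2)
  supra <- which(abs(t_obs) > t_crit)

  arr <- array(-Inf, dim = grid$shape)
  arr[grid$mask_idx] <- abs(d_obs)
  pk_lin <- local_maxima(arr, grid$mask_idx[supra], grid$shape)
  pk_pos <- match(pk_lin, grid$mask_idx)

  id <- sprintf("synth%02d", study_index)
  peaks <- data.frame(
    study_id = rep(id, length(pk_pos)),
    x = grid$mask_mm[pk_pos, 1], y = grid$mask_mm[pk_pos, 2],
    z = grid$mask_mm[pk_pos, 3],
    space = rep("MNI", length(pk_pos)),
    direction = ifelse(d_obs[pk_pos] < 0, "decrease", "increase"),
    stat_type = rep("t", length(pk_pos)),
    stat_value = t_obs[pk_pos],
    stringsAsFactors = FALSE)
  if (!length(pk_pos)) peaks <- empty_peak_df()
  attr(peaks, "n_suprathreshold") <- length(supra)

  study <- data.frame(
    study_id = id, n_patients = n1, male_patients = male_p,
    n_controls = n2, male_controls = male_c,
    age_patient_mean = round(covs$age_patient_mean, 2), age_patient_sd = 6,
    age_control_mean = round(covs$age_patient_mean - stats::rnorm(1, 0, 1.5), 2),
    age_control_sd = 6,
    updrs3_mean = round(covs$updrs3_mean, 2), updrs3_sd = 9,
    hy_mean = NA_real_, hy_sd = NA_real_,
    duration_mean = round(covs$duration_mean, 2), duration_sd = 1.2,
    mmse_mean = round(covs$mmse_mean, 2), mmse_sd = 3,
    fab_mean = NA_real_, fab_sd = NA_real_,
    scanner_tesla = sample(c(1.5, 3.0), 1),
    software = "synthetic", smoothing_fwhm_mm = 8,
    threshold_p = truth$study_threshold_p, threshold_corrected = FALSE,
    quality_score = 10, subgroup_tags = "synthetic",
    stringsAsFactors = FALSE)
  list(study = study, peaks = peaks)
}

#' Simulate a complete multi-study coordinate dataset
#'
#' Runs [simulate_study()] `k_studies` times under the seed recorded in the
#' truth spec, and returns the study table, the per-study peak tables, and
#' the truth record itself so downstream tests can score recovery.
#'
#' @param truth a [truth_spec()].
#' @param grid a [brain_grid()].
#' @return list with `studies` (a `study_table`), `peaks` (a
#'   `peak_tables` list) and `truth`.
#' @examples
#' g <- brain_grid(voxel_mm = 4, bbox = cbind(c(-40, -40, -40), c(40, 40, 40)))
#' ds <- simulate_dataset(truth_spec(k_studies = 4, seed = 7), g)
#' sapply(ds$peaks, nrow)
#' @export
simulate_dataset <- function(truth, grid) {
  set.seed(truth$seed)
  sims <- lapply(seq_len(truth$k_studies),
                 function(i) simulate_study(truth, grid, i))
  studies <- do.call(rbind, lapply(sims, `[[`, "study"))
  validate_study_table(studies)
  class(studies) <- c("study_table", "data.frame")
  pk <- do.call(rbind, c(lapply(sims, `[[`, "peaks"), list(empty_peak_df())))
  list(studies = studies, peaks = split_peaks(pk, studies), truth = truth)
}

#' Serialize / restore a truth record
#'
#' The truth spec round-trips through JSON so simulated datasets can be
#' archived next to their generating parameters.
#' @param truth a [truth_spec()].
#' @param path JSON file path.
#' @return `read_truth` returns a [truth_spec()].
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  clusters <- x$clusters
  if (is.data.frame(clusters))
    clusters <- lapply(seq_len(nrow(clusters)), function(i)
      list(center = unlist(clusters$center[i]), radius_mm = clusters$radius_mm[i],
           g = clusters$g[i]))
  truth_spec(clusters = clusters, k_studies = x$k_studies,
             n_range = x$n_range, tau2_true = x$tau2_true,
             study_threshold_p = x$study_threshold_p,
             covariate_links = x$covariate_links, seed = x$seed)
}
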