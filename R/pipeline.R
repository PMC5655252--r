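#' Read a pipeline run configuration
#'
#' YAML schema (all analysis parameters default to the published defaults):
#' ```yaml
#' study_table: path/to/studies.tsv
#' peak_tables: path/to/peaks.tsv      # file or directory
#' mask: null                          # optional NIfTI mask
#' voxel_mm: 2
#' kernel: {fwhm_mm: 20, truncation_radius_mm: 30}
#' threshold: {p_voxel: 0.005, min_peak_abs_z: 1, min_extent_voxels: 10}
#' metareg_threshold: {p_voxel: 0.0005, min_extent_voxels: 11}
#' covariates: [age_patient_mean, updrs3_mean, mmse_mean, duration_mean,
#'              hy_mean, fab_mean, male_ratio, scanner_tesla]
#' min_covariate_studies: 10
#' subgroup_tag: PSP-RS-criteria
#' egger_alpha: 0.05
#' seed: 1
#' output_dir: results
#' ```
#'
#' @param path YAML file.
#' @return a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(voxel_mm = 2, kernel = list(), threshold = list(),
                   metareg_threshold = list(p_voxel = 5e-4,
                                            min_extent_voxels = 11),
                   covariates = c("age_patient_mean", "updrs3_mean",
                                  "mmse_mean", "duration_mean", "hy_mean",
                                  "fab_mean", "male_ratio", "scanner_tesla"),
                   min_covariate_studies = 10, subgroup_tag = NULL,
                   egger_alpha = 0.05, seed = 1L, output_dir = "results",
                   mask = NULL)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$study_table) || is.null(cfg$peak_tables))
    stop("config must name study_table and peak_tables")
  class(cfg) <- "run_config"
  cfg
}

config_grid <- function(cfg) {
  if (!is.null(cfg$mask)) read_mask_nifti(cfg$mask, cfg$voxel_mm)
  else brain_grid(voxel_mm = cfg$voxel_mm)
}

#' Run the full analysis pipeline from a configuration
#'
#' Orchestrates the whole workflow: load and validate inputs, fit the main
#' meta-analysis, the tagged subgroup (if configured), jackknife,
#' heterogeneity, Egger tests, covariate meta-regressions (with the
#' availability rule), and the cohort-level demographic meta-analyses;
#' writes cluster tables as TSV, statistical maps as NIfTI-1, and a JSON
#' summary with full provenance (config, seed, package version) into
#' `output_dir`. Reduction and increase tables are both always written,
#' even when empty.
#'
#' @param cfg a `run_config` (see [read_run_config()]) or path to one.
#' @param write_maps write NIfTI maps (default TRUE; tests disable it).
#' @return invisible list with all result objects.
#' @export
run_pipeline <- function(cfg, write_maps = TRUE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  set.seed(cfg$seed)
  studies <- load_study_table(cfg$study_table)
  peaks <- load_peak_tables(cfg$peak_tables, studies)
  grid <- config_grid(cfg)
  kernel <- do.call(kernel_spec, cfg$kernel)
  thr <- do.call(threshold_spec, cfg$threshold)
  mthr <- do.call(threshold_spec, cfg$metareg_threshold)

  fit <- sdm_meta(studies, peaks, grid = grid, kernel = kernel, threshold = thr)
  jk <- sdm_jackknife(fit)
  het <- sdm_heterogeneity(fit)
  eg <- if (nrow(fit$clusters)) sdm_egger(fit, cfg$egger_alpha) else NULL

  covs <- as.list(cfg$covariates)
  names(covs) <- unlist(cfg$covariates)
  covs <- lapply(names(covs), function(nm) {
    if (nm == "male_ratio") studies$male_patients / studies$n_patients
    else studies[[nm]]
  })
  names(covs) <- unlist(cfg$covariates)
  mreg <- sdm_metaregression(fit, covs, cfg$min_covariate_studies, mthr)

  sub <- if (!is.null(cfg$subgroup_tag))
    run_subgroup(studies, peaks, cfg$subgroup_tag, grid = grid,
                 kernel = kernel, threshold = thr) else NULL

  age <- tryCatch(pooled_age_smd(studies), error = function(e) NULL)
  sex <- tryCatch(pooled_sex_rr(studies), error = function(e) NULL)

  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  eg_red <- if (!is.null(eg)) eg[fit$clusters$sign == "reduction", , drop = FALSE]
  eg_inc <- if (!is.null(eg)) eg[fit$clusters$sign == "increase", , drop = FALSE]
  write_cluster_tsv(fit$reductions, file.path(out, "clusters_reduction.tsv"), eg_red)
  write_cluster_tsv(fit$increases, file.path(out, "clusters_increase.tsv"), eg_inc)
  if (write_maps) {
    write_map_nifti(fit$pooled$effect, file.path(out, "pooled_effect.nii.gz"))
    write_map_nifti(fit$pooled$z, file.path(out, "pooled_z.nii.gz"))
    write_map_nifti(het$Q, file.path(out, "heterogeneity_Q.nii.gz"))
  }
  summary <- list(
    provenance = list(package = "sdmeta",
                      version = as.character(utils::packageVersion("sdmeta")),
                      seed = cfg$seed, config = unclass(cfg),
                      timestamp = format(Sys.time(), tz = "UTC")),
    n_studies = nrow(studies),
    n_patients = sum(studies$n_patients),
    n_controls = sum(studies$n_controls),
    n_reduction_clusters = nrow(fit$reductions),
    n_increase_clusters = nrow(fit$increases),
    jackknife = list(n = jk$n, replication = as.list(jk$replication)),
    heterogeneity_clusters = nrow(het$clusters),
    metaregression = lapply(mreg, function(m)
      if (m$skipped) list(skipped = TRUE, reason = m$reason)
      else list(skipped = FALSE, n_studies_used = m$n_studies_used,
                n_clusters = nrow(m$clusters))),
    subgroup = if (!is.null(sub)) list(tag = sub$subgroup_tag,
                                       n_studies = sub$subgroup_size,
                                       n_reduction_clusters = nrow(sub$reductions)),
    age_smd = if (!is.null(age)) age[c("estimate", "ci_low", "ci_high", "p")],
    sex_rr = if (!is.null(sex)) sex[c("estimate", "ci_low", "ci_high", "p")])
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(fit = fit, jackknife = jk, heterogeneity = het, egger = eg,
                 metaregression = mreg, subgroup = sub, age_smd = age,
                 sex_rr = sex, summary = summary))
}

# cluster table TSV mirroring the published table layout
write_cluster_tsv <- function(clusters, path, egger = NULL) {
  d <- cluster_df(clusters)
  if (!is.null(egger) && nrow(d)) d$egger_p <- egger$p[seq_len(nrow(d))]
  utils::write.table(format(d, digits = 6), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
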