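#' Read a study metadata table
#'
#' Reads the tab-separated study table (one row per included study) used
#' throughout the package: sample sizes, male counts, age, clinical scores
#' (UPDRS-III, H&Y, illness duration, MMSE, FAB), scanner field strength,
#' analysis software, smoothing FWHM, statistical threshold and quality
#' score. Missing cells are encoded as the literal string `NA` and are kept
#' missing — never imputed at this stage.
#'
#' The packaged fixture `psp_vbm_studies.tsv` transcribes the demographic,
#' clinical and imaging characteristics of the 18 voxel-based morphometry
#' studies (284 patients with progressive supranuclear palsy, 367 healthy
#' controls) pooled in the meta-analysis this package re-implements; see
#' [sdmeta_example_studies()].
#'
#' @param path path to a TSV file with the documented header.
#' @return a `data.frame` of class `study_table`, one row per study.
#' @seealso [load_peak_tables()], [summarize_availability()]
#' @export
load_study_table <- function(path) {
  if (!file.exists(path)) stop("study table not found: ", path)
  d <- utils::read.delim(path, na.strings = "NA", stringsAsFactors = FALSE,
                         check.names = FALSE)
  required <- c("study_id", "n_patients", "male_patients", "n_controls",
                "male_controls", "age_patient_mean", "age_patient_sd",
                "age_control_mean", "age_control_sd", "updrs3_mean",
                "updrs3_sd", "hy_mean", "hy_sd", "duration_mean",
                "duration_sd", "mmse_mean", "mmse_sd", "fab_mean", "fab_sd",
                "scanner_tesla", "software", "smoothing_fwhm_mm",
                "threshold_p", "threshold_corrected", "quality_score",
                "subgroup_tags")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop("study table is missing columns: ", paste(missing_cols, collapse = ", "))
  d <- d[, required]
  validate_study_table(d)
  class(d) <- c("study_table", "data.frame")
  d
}

validate_study_table <- function(d) {
  if (nrow(d) == 0L) return(invisible(d))
  check_row <- function(cond, col, msg) {
    bad <- which(!cond)
    if (length(bad))
      stop(sprintf("study table row %d, column '%s': %s", bad[1], col, msg))
  }
  if (anyDuplicated(d$study_id))
    stop("duplicate study_id: ", d$study_id[duplicated(d$study_id)][1])
  check_row(!is.na(d$n_patients) & d$n_patients >= 1, "n_patients",
            "must be a positive integer")
  check_row(!is.na(d$n_controls) & d$n_controls >= 1, "n_controls",
            "must be a positive integer")
  check_row(is.na(d$male_patients) | d$male_patients <= d$n_patients,
            "male_patients", "male count exceeds group size")
  check_row(is.na(d$male_controls) | d$male_controls <= d$n_controls,
            "male_controls", "male count exceeds group size")
  check_row(is.na(d$quality_score) | d$quality_score <= 10, "quality_score",
            "must be at most 10")
  check_row(is.na(d$scanner_tesla) | d$scanner_tesla %in% c(1.5, 3.0),
            "scanner_tesla", "must be 1.5, 3.0 or NA")
  invisible(d)
}

#' Write a study table in canonical form
#'
#' Serialization is canonical (fixed column order, `NA` sentinel, no
#' quoting), so a load/write round-trip of a canonical file is
#' byte-identical.
#' @param studies a `study_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(studies, path) {
  utils::write.table(studies, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Path to the packaged study-table fixture
#'
#' The transcribed study table of the 18 progressive supranuclear palsy VBM
#' studies. Subgroup tags: `PSP-RS-criteria` marks the 14 studies whose
#' patients were diagnosed by the NINDS-SPSP criteria; `mixed-subtypes` and
#' `nfvPPA-pathology` mark the rest (the published account gives only the
#' counts, so the attribution of the mixed-subtype tags to specific studies
#' is this package's documented assignment).
#' @return file path of the TSV fixture.
#' @export
sdmeta_example_studies <- function() {
  system.file("extdata", "psp_vbm_studies.tsv", package = "sdmeta", mustWork = TRUE)
}

#' Read per-study peak-coordinate tables
#'
#' Accepts either one TSV holding all studies' peaks or a directory of
#' per-study TSVs, with columns `study_id, x, y, z, space, direction,
#' stat_type, stat_value`. Every peak's `study_id` must match the study
#' table; a study with no rows is allowed and encodes "no significant
#' differences reported".
#'
#' @param path TSV file or directory of TSV files.
#' @param studies the `study_table` the peaks belong to.
#' @return named list of `data.frame`s, one per study (possibly zero-row),
#'   in study-table order; class `peak_tables`.
#' @export
load_peak_tables <- function(path, studies) {
  cols <- c("study_id", "x", "y", "z", "space", "direction", "stat_type",
            "stat_value")
  read_one <- function(f) {
    d <- utils::read.delim(f, na.strings = "NA", stringsAsFactors = FALSE)
    miss <- setdiff(cols, names(d))
    if (length(miss))
      stop("peak table ", f, " missing columns: ", paste(miss, collapse = ", "))
    d[, cols]
  }
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tsv$", full.names = TRUE)
    d <- do.call(rbind, lapply(files, read_one))
    if (is.null(d)) d <- empty_peak_df()
  } else if (file.exists(path)) {
    d <- read_one(path)
  } else stop("peak table path not found: ", path)
  validate_peaks(d, studies)
  split_peaks(d, studies)
}

empty_peak_df <- function() {
  data.frame(study_id = character(), x = numeric(), y = numeric(),
             z = numeric(), space = character(), direction = character(),
             stat_type = character(), stat_value = numeric(),
             stringsAsFactors = FALSE)
}

validate_peaks <- function(d, studies) {
  unknown <- setdiff(unique(d$study_id), studies$study_id)
  if (length(unknown))
    stop("peaks reference unknown study_id: ", paste(unknown, collapse = ", "))
  if (nrow(d)) {
    for (cn in c("x", "y", "z")) {
      if (!is.numeric(d[[cn]]) || any(!is.finite(d[[cn]])))
        stop("non-numeric or non-finite coordinate in column '", cn, "'")
    }
    if (any(!d$space %in% c("MNI", "Talairach")))
      stop("peak 'space' must be MNI or Talairach")
    if (any(!d$direction %in% c("decrease", "increase")))
      stop("peak 'direction' must be decrease or increase")
    if (any(!d$stat_type %in% c("t", "z", "p_only", "unreported")))
      stop("peak 'stat_type' must be one of t, z, p_only, unreported")
  }
  invisible(d)
}

split_peaks <- function(d, studies) {
  out <- lapply(studies$study_id, function(id) {
    pk <- d[d$study_id == id, , drop = FALSE]
    rownames(pk) <- NULL
    pk
  })
  names(out) <- studies$study_id
  class(out) <- "peak_tables"
  out
}

#' Write peak tables as a single TSV
#'
#' Inverse of [load_peak_tables()] (single-file form).
#' @param peaks a `peak_tables` list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peak_tables <- function(peaks, path) {
  d <- do.call(rbind, c(unname(peaks), list(empty_peak_df())))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# Lancaster icbm2tal affine (SPM flavour): maps MNI/ICBM mm to Talairach mm.
# Talairach peaks are brought into MNI space with its inverse.
ICBM2TAL <- matrix(c(0.9254,  0.0024, -0.0118, -1.0207,
                     -0.0048, 0.9316, -0.0871, -1.7667,
                     0.0152,  0.0883,  0.8924,  4.0926,
                     0, 0, 0, 1), nrow = 4, byrow = TRUE)

#' Convert peak coordinates to MNI space
#'
#' MNI input is returned unchanged. Talairach input is mapped through the
#' inverse of the Lancaster `icbm2tal` affine (the SPM-flavoured pooled
#' transform); the mapping is deterministic and invertible.
#'
#' @param xyz numeric vector of length 3, or a matrix with 3 columns (mm).
#' @param space `"MNI"` or `"Talairach"`; recycled over rows.
#' @return coordinates in MNI mm, same shape as the input.
#' @examples
#' convert_to_mni(c(10, -20, 30), "Talairach")
#' @export
convert_to_mni <- function(xyz, space) {
  vec_in <- is.null(dim(xyz))
  if (vec_in) xyz <- matrix(xyz, ncol = 3L, byrow = TRUE)
  if (any(!space %in% c("MNI", "Talairach")))
    stop("unknown coordinate space: ", paste(setdiff(space, c("MNI", "Talairach")), collapse = ", "))
  space <- rep_len(space, nrow(xyz))
  tal <- space == "Talairach"
  if (any(tal)) {
    inv <- solve(ICBM2TAL)
    pts <- cbind(xyz[tal, , drop = FALSE], 1) %*% t(inv)
    xyz[tal, ] <- pts[, 1:3]
  }
  if (vec_in && nrow(xyz) == 1L) drop(xyz) else xyz
}

#' Summarize covariate availability across studies
#'
#' For each study-level covariate, the number of studies reporting a
#' non-missing mean and the range of the reported means — the accounting
#' that drives the meta-regression availability rule (a covariate is only
#' analyzed when at least `min_covariate_studies` studies report it).
#'
#' @param studies a `study_table`.
#' @param covariates character vector of mean-valued columns to summarize.
#' @return data.frame with columns `covariate`, `n_reporting`, `min`, `max`.
#' @examples
#' s <- load_study_table(sdmeta_example_studies())
#' summarize_availability(s)
#' @export
summarize_availability <- function(studies,
                                   covariates = c("age_patient_mean",
                                                  "updrs3_mean", "hy_mean",
                                                  "duration_mean",
                                                  "mmse_mean", "fab_mean")) {
  if (nrow(studies) == 0L) stop("empty study table")
  rows <- lapply(covariates, function(cv) {
    x <- studies[[cv]]
    if (is.null(x)) stop("unknown covariate column: ", cv)
    x <- x[!is.na(x)]
    data.frame(covariate = cv, n_reporting = length(x),
               min = if (length(x)) min(x) else NA_real_,
               max = if (length(x)) max(x) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Peaks of all studies converted to MNI, as one matrix per study
#'
#' Helper used by the reconstruction step: converts each study's peaks to
#' MNI mm and attaches the signed effect size for each peak (from the
#' reported statistic, or imputed from the study threshold when the peak
#' statistic is unreported; see [impute_peak_effect()]).
#'
#' @param peaks a `peak_tables` list.
#' @param studies the matching `study_table`.
#' @return list (per study) of data.frames with columns x, y, z (MNI mm),
#'   g (signed effect size), imputed (logical).
#' @export
prepare_peaks <- function(peaks, studies) {
  out <- lapply(studies$study_id, function(id) {
    pk <- peaks[[id]]
    st <- studies[studies$study_id == id, ]
    if (is.null(pk) || nrow(pk) == 0L)
      return(data.frame(x = numeric(), y = numeric(), z = numeric(),
                        g = numeric(), imputed = logical()))
    mni <- convert_to_mni(as.matrix(pk[, c("x", "y", "z")]), pk$space)
    sgn <- ifelse(pk$direction == "decrease", -1, 1)
    g <- numeric(nrow(pk))
    imputed <- logical(nrow(pk))
    for (i in seq_len(nrow(pk))) {
      g[i] <- switch(pk$stat_type[i],
        t = t_to_hedges_g(pk$stat_value[i], st$n_patients, st$n_controls),
        z = t_to_hedges_g(z_to_t(pk$stat_value[i], st$n_patients + st$n_controls - 2),
                          st$n_patients, st$n_controls),
        {
          imputed[i] <- TRUE
          impute_peak_effect(pk$stat_type[i], st$threshold_p,
                             st$n_patients, st$n_controls)
        })
      # reported statistics carry their own sign in stat_value when signed;
      # direction is authoritative for magnitude-only reports
      if (pk$stat_type[i] %in% c("t", "z")) {
        if (!is.na(pk$stat_value[i]) && pk$stat_value[i] >= 0) g[i] <- abs(g[i]) * sgn[i]
      } else {
        g[i] <- abs(g[i]) * sgn[i]
      }
    }
    data.frame(x = mni[, 1], y = mni[, 2], z = mni[, 3], g = g,
               imputed = imputed)
  })
  names(out) <- studies$study_id
  out
}
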