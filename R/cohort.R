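# shared scalar DerSimonian-Laird pooling on (yi, vi)
dl_pool_scalar <- function(yi, vi, level = 0.95) {
  k <- length(yi)
  if (k < 2L) stop("at least 2 usable studies are required")
  tau2 <- dl_tau2(yi, vi)
  w <- 1 / (vi + tau2)
  est <- sum(w * yi) / sum(w)
  se <- sqrt(1 / sum(w))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  z <- est / se
  list(estimate = est, se = se, ci_low = est - zq * se,
       ci_high = est + zq * se, z = z,
       p = 2 * stats::pnorm(-abs(z)), tau2 = tau2, k_studies = k,
       model = "random")
}

#' Pooled standardized mean difference in age (patients vs controls)
#'
#' Computes each study's Hedges-g standardized difference in mean age
#' between patients and controls (pooled SD, small-sample correction) and
#' combines them with DerSimonian-Laird random-effects inverse-variance
#' weighting. Studies missing any of the four age summaries are excluded
#' and counted.
#'
#' @param studies a `study_table`.
#' @return list of class `pooled_scalar`: `estimate`, `ci_low`, `ci_high`,
#'   `z`, `p`, `k_studies`, `k_excluded`, `model`, plus per-study `yi`/`vi`.
#' @examples
#' pooled_age_smd(load_study_table(sdmeta_example_studies()))
#' @export
pooled_age_smd <- function(studies) {
  need <- c("age_patient_mean", "age_patient_sd", "age_control_mean",
            "age_control_sd")
  ok <- stats::complete.cases(studies[, need])
  d <- studies[ok, ]
  if (nrow(d) < 2L) stop("fewer than 2 studies with complete age data")
  n1 <- d$n_patients; n2 <- d$n_controls
  sp <- sqrt(((n1 - 1) * d$age_patient_sd^2 + (n2 - 1) * d$age_control_sd^2) /
               (n1 + n2 - 2))
  g <- (d$age_patient_mean - d$age_control_mean) / sp * j_correction(n1, n2)
  vi <- g_variance(g, n1, n2)
  res <- dl_pool_scalar(g, vi)
  res$k_excluded <- sum(!ok)
  res$yi <- g; res$vi <- vi; res$study_id <- d$study_id
  res$measure <- "SMD (age, patients - controls)"
  class(res) <- "pooled_scalar"
  res
}

#' Pooled relative risk of male sex (patients vs controls)
#'
#' Each study's log relative risk of being male in the patient group versus
#' the control group, with the standard delta-method variance
#' `1/a - 1/n1 + 1/c - 1/n2`, pooled by DerSimonian-Laird random effects and
#' exponentiated. A zero cell triggers a 0.5 continuity correction (logged
#' via the `continuity_corrected` element). Orientation: male proportion in
#' patients over male proportion in controls.
#'
#' @param studies a `study_table`.
#' @return list of class `pooled_scalar` (estimate and CI on the RR scale).
#' @examples
#' pooled_sex_rr(load_study_table(sdmeta_example_studies()))
#' @export
pooled_sex_rr <- function(studies) {
  ok <- stats::complete.cases(studies[, c("male_patients", "male_controls")])
  d <- studies[ok, ]
  if (nrow(d) < 2L) stop("fewer than 2 studies with male counts")
  a <- d$male_patients; n1 <- d$n_patients
  b <- d$male_controls; n2 <- d$n_controls
  cc <- a == 0 | b == 0 | a == n1 | b == n2
  a <- a + 0.5 * cc; b <- b + 0.5 * cc
  m1 <- n1 + 1 * cc; m2 <- n2 + 1 * cc
  yi <- log((a / m1) / (b / m2))
  vi <- 1 / a - 1 / m1 + 1 / b - 1 / m2
  res <- dl_pool_scalar(yi, vi)
  res$estimate <- exp(res$estimate)
  res$ci_low <- exp(res$ci_low)
  res$ci_high <- exp(res$ci_high)
  res$k_excluded <- sum(!ok)
  res$continuity_corrected <- d$study_id[cc]
  res$yi <- yi; res$vi <- vi; res$study_id <- d$study_id
  res$measure <- "relative risk (male, patients vs controls)"
  class(res) <- "pooled_scalar"
  res
}

#' @export
print.pooled_scalar <- function(x, ...) {
  cat(sprintf("%s\n  pooled estimate %.3f (95%% CI %.3f to %.3f), z = %.3f, p = %.4g\n  %d studies pooled (%d excluded for missing data), %s-effects (DL)\n",
              x$measure, x$estimate, x$ci_low, x$ci_high, x$z, x$p,
              x$k_studies, x$k_excluded, x$model))
  invisible(x)
}
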