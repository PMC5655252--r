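#' Hedges g from a two-sample t statistic
#'
#' Converts a reported peak t value to a small-sample-corrected standardized
#' mean difference: `g = t * sqrt(1/n1 + 1/n2) * J` with the correction
#' `J = 1 - 3 / (4*(n1 + n2 - 2) - 1)`. The sign of `g` equals the sign of
#' `t`.
#'
#' @param t t statistic (signed).
#' @param n1,n2 group sizes (patients, controls), each at least 2.
#' @return signed effect size g.
#' @examples
#' t_to_hedges_g(2, 20, 20)
#' @export
t_to_hedges_g <- function(t, n1, n2) {
  check_groups(n1, n2)
  if (any(!is.finite(t))) stop("t must be finite")
  t * sqrt(1 / n1 + 1 / n2) * j_correction(n1, n2)
}

j_correction <- function(n1, n2) 1 - 3 / (4 * (n1 + n2 - 2) - 1)

check_groups <- function(n1, n2) {
  if (any(is.na(n1)) || any(is.na(n2)) || any(n1 < 2) || any(n2 < 2))
    stop("group sizes must be at least 2")
  invisible(TRUE)
}

#' Sampling variance of Hedges g
#'
#' `v = (n1 + n2)/(n1*n2) + g^2 / (2*(n1 + n2))`; strictly positive.
#'
#' @param g effect size.
#' @param n1,n2 group sizes.
#' @return variance of g.
#' @examples
#' g_variance(0, 20, 20)  # 0.1
#' @export
g_variance <- function(g, n1, n2) {
  check_groups(n1, n2)
  (n1 + n2) / (n1 * n2) + g^2 / (2 * (n1 + n2))
}

# two-tailed z statistic -> equivalent t with df degrees of freedom
z_to_t <- function(z, df) {
  p <- 2 * stats::pnorm(-abs(z))
  p <- pmax(p, .Machine$double.xmin)
  sign(z) * stats::qt(1 - p / 2, df)
}

#' Lower-bound effect size for peaks reported without a statistic
#'
#' Studies sometimes report only that a peak survived their voxel threshold.
#' The conventional lower-bound imputation is the effect size of the
#' two-tailed t quantile at the study's reported threshold p with
#' `df = n1 + n2 - 2`. The returned magnitude is unsigned; the caller signs
#' it by the peak's direction and flags it as imputed in provenance.
#'
#' @param stat_type `"p_only"` or `"unreported"`.
#' @param study_threshold_p the study's voxel-level threshold p.
#' @param n1,n2 group sizes.
#' @return unsigned effect-size magnitude.
#' @examples
#' impute_peak_effect("p_only", 0.001, 20, 20)
#' @export
impute_peak_effect <- function(stat_type, study_threshold_p, n1, n2) {
  if (!stat_type %in% c("p_only", "unreported"))
    stop("impute_peak_effect only applies to stat_type p_only or unreported")
  if (is.na(study_threshold_p) || study_threshold_p <= 0 || study_threshold_p >= 1)
    stop("a valid study threshold p is required to impute a peak effect size")
  check_groups(n1, n2)
  tq <- stats::qt(1 - study_threshold_p / 2, df = n1 + n2 - 2)
  abs(t_to_hedges_g(tq, n1, n2))
}
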