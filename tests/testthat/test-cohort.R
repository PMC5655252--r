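mk_studies <- function(df) {
  base <- as.data.frame(fixture_studies())[0, ]
  for (nm in names(df)) base[seq_len(nrow(df)), nm] <- df[[nm]]
  base$study_id <- sprintf("s%d", seq_len(nrow(df)))
  for (nm in setdiff(names(base), names(df)))
    if (!nm %in% "study_id") base[[nm]] <- base[[nm]]
  class(base) <- c("study_table", "data.frame")
  base
}

test_that("identical group means give a zero pooled age SMD", {
  s <- mk_studies(data.frame(
    n_patients = c(20, 15), n_controls = c(20, 18),
    age_patient_mean = c(65, 70), age_patient_sd = c(5, 6),
    age_control_mean = c(65, 70), age_control_sd = c(4, 7)))
  r <- pooled_age_smd(s)
  expect_equal(r$estimate, 0)
  expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
})

test_that("pooled age SMD matches an independent DL computation", {
  s <- mk_studies(data.frame(
    n_patients = c(12, 20, 16), n_controls = c(14, 22, 19),
    age_patient_mean = c(67.5, 70.3, 64.2),
    age_patient_sd = c(6.6, 6.4, 5.1),
    age_control_mean = c(60.0, 71.5, 66.0),
    age_control_sd = c(5.8, 7.2, 6.0)))
  r <- pooled_age_smd(s)
  # brute-force oracle: per-study Hedges g then DL pooling, all explicit
  n1 <- s$n_patients; n2 <- s$n_controls
  sp <- sqrt(((n1 - 1) * s$age_patient_sd^2 + (n2 - 1) * s$age_control_sd^2) /
               (n1 + n2 - 2))
  J <- 1 - 3 / (4 * (n1 + n2 - 2) - 1)
  yi <- (s$age_patient_mean - s$age_control_mean) / sp * J
  vi <- (n1 + n2) / (n1 * n2) + yi^2 / (2 * (n1 + n2))
  w <- 1 / vi; gfe <- sum(w * yi) / sum(w)
  Q <- sum(w * (yi - gfe)^2); C <- sum(w) - sum(w^2) / sum(w)
  t2 <- max(0, (Q - 2) / C); ws <- 1 / (vi + t2)
  expect_equal(r$estimate, sum(ws * yi) / sum(ws), tolerance = 1e-10)
  expect_equal(r$ci_high - r$ci_low,
               2 * qnorm(0.975) * sqrt(1 / sum(ws)), tolerance = 1e-10)
  skip_if_not_installed("metafor")
  es <- metafor::escalc("SMD", m1i = s$age_patient_mean,
                        sd1i = s$age_patient_sd, n1i = n1,
                        m2i = s$age_control_mean, sd2i = s$age_control_sd,
                        n2i = n2)
  # metafor's large-sample SMD variance differs slightly in the g^2 term,
  # so agreement is statistical, not bitwise
  mf <- metafor::rma(es$yi, es$vi, method = "DL")
  expect_equal(r$estimate, as.numeric(coef(mf)), tolerance = 1e-3)
})

test_that("swapping patient and control columns negates the SMD", {
  s <- mk_studies(data.frame(
    n_patients = c(12, 20), n_controls = c(14, 22),
    age_patient_mean = c(67.5, 70.3), age_patient_sd = c(6.6, 6.4),
    age_control_mean = c(60.0, 71.5), age_control_sd = c(5.8, 7.2)))
  sw <- s
  sw[, c("n_patients", "n_controls")] <- s[, c("n_controls", "n_patients")]
  sw[, c("age_patient_mean", "age_control_mean")] <-
    s[, c("age_control_mean", "age_patient_mean")]
  sw[, c("age_patient_sd", "age_control_sd")] <-
    s[, c("age_control_sd", "age_patient_sd")]
  expect_equal(pooled_age_smd(sw)$estimate, -pooled_age_smd(s)$estimate,
               tolerance = 1e-10)
})

test_that("log relative risk and its variance match the 2x2 closed form", {
  s <- mk_studies(data.frame(
    n_patients = c(20, 30), n_controls = c(25, 28),
    male_patients = c(12, 21), male_controls = c(13, 12)))
  r <- pooled_sex_rr(s)
  yi <- log((c(12, 21) / c(20, 30)) / (c(13, 12) / c(25, 28)))
  vi <- 1 / c(12, 21) - 1 / c(20, 30) + 1 / c(13, 12) - 1 / c(25, 28)
  expect_equal(r$yi, yi, tolerance = 1e-12)
  expect_equal(r$vi, vi, tolerance = 1e-12)
  t2 <- dl_tau2(yi, vi); w <- 1 / (vi + t2)
  expect_equal(r$estimate, exp(sum(w * yi) / sum(w)), tolerance = 1e-12)
})

test_that("identical male proportions give RR exactly 1 and inversion works", {
  s <- mk_studies(data.frame(
    n_patients = c(20, 40), n_controls = c(30, 20),
    male_patients = c(10, 20), male_controls = c(15, 10)))
  expect_equal(pooled_sex_rr(s)$estimate, 1)
  s2 <- mk_studies(data.frame(
    n_patients = c(20, 30), n_controls = c(25, 28),
    male_patients = c(12, 21), male_controls = c(13, 12)))
  sw <- s2
  sw[, c("n_patients", "n_controls")] <- s2[, c("n_controls", "n_patients")]
  sw[, c("male_patients", "male_controls")] <-
    s2[, c("male_controls", "male_patients")]
  expect_equal(pooled_sex_rr(sw)$estimate, 1 / pooled_sex_rr(s2)$estimate,
               tolerance = 1e-10)
})

test_that("zero-male groups are continuity-corrected rather than fatal", {
  s <- mk_studies(data.frame(
    n_patients = c(10, 15), n_controls = c(12, 18),
    male_patients = c(0, 9), male_controls = c(6, 8)))
  r <- pooled_sex_rr(s)
  expect_true(is.finite(r$estimate))
  expect_equal(r$continuity_corrected, "s1")
})

test_that("missing-data studies are excluded and counted", {
  s <- fixture_studies()
  a <- pooled_age_smd(s)
  expect_equal(a$k_studies, 15)
  expect_equal(a$k_excluded, 3)
  rr <- pooled_sex_rr(s)
  expect_equal(rr$k_studies, 17)
  expect_equal(rr$k_excluded, 1)
})
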