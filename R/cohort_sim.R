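## Synthetic heavy-smoker screening cohort.
##
## Marginals are calibrated to the published cohort descriptives of a
## male lung-cancer-screening population (age 59.4 +/- 5.2 y, median
## pack-years 34.0 with quartiles 28.0-45.6, 59.1% current smokers,
## median AWT_3.5 0.57 mm with quartiles 0.44-0.74, Perc15 -920 HU with
## quartiles -930 to -907, FEV1%predicted 98.2 +/- 19.7); the structural
## model generates FEV1%predicted linearly from log-AWT and Perc15 with
## the multivariate coefficients -31.28 (%pred per log-mm) and 0.342
## (%pred per HU). Skewed medians/quartiles become log-normal parameters
## via the normal-IQR identity IQR = 2 * z(0.75) * sd, z(0.75) = 0.6745.

Z75 <- qnorm(0.75)

#' Default cohort simulation parameters
#'
#' Location/scale parameters are derived from the published medians,
#' quartiles and means; the intercept is solved so the mean of
#' FEV1%predicted equals 98.2 at the covariate means, and the residual SD
#' so the total SD is 19.7. The log-AWT/Perc15 correlation is not a
#' published number; the default +0.20 encodes the weak positive
#' association between log-AWT and Perc15 reported in univariate
#' analyses.
#'
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @param rho_awt_perc15 Correlation between log-AWT and Perc15.
#' @return A `cohort_params` list.
#' @export
default_params <- function(n = 492L, seed = 1L, rho_awt_perc15 = 0.20) {
  awt_log_sd <- (log(0.74) - log(0.44)) / (2 * Z75)
  perc15_sd <- (-907 - (-930)) / (2 * Z75)
  beta_logawt <- -31.28
  beta_perc15 <- 0.342
  awt_log_mu <- log(0.57)
  perc15_mu <- -920
  beta0 <- 98.2 - beta_logawt * awt_log_mu - beta_perc15 * perc15_mu
  explained_var <- beta_logawt^2 * awt_log_sd^2 +
    beta_perc15^2 * perc15_sd^2 +
    2 * beta_logawt * beta_perc15 * rho_awt_perc15 * awt_log_sd * perc15_sd
  resid_var <- 19.7^2 - explained_var
  if (resid_var <= 0) stop_domain("explained variance exceeds the total")
  prevalence <- c(cmh = 0.297, cough = 0.327, dyspnea = 0.284,
                  wheezing = 0.253)
  slope <- 1.5  # per log-mm; direction (thicker walls in symptomatic)
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         age_mean = 59.4, age_sd = 5.2,
         packyears_log_mu = log(34.0),
         packyears_log_sd = (log(45.6) - log(28.0)) / (2 * Z75),
         current_smoking_prob = 0.591,
         awt_log_mu = awt_log_mu, awt_log_sd = awt_log_sd,
         perc15_mu = perc15_mu, perc15_sd = perc15_sd,
         rho_awt_perc15 = rho_awt_perc15,
         beta0 = beta0, beta_logawt = beta_logawt,
         beta_perc15 = beta_perc15, resid_sd = sqrt(resid_var),
         symptom_slopes = setNames(rep(slope, 4), names(prevalence)),
         symptom_intercepts = qlogis_safe(prevalence) - slope * awt_log_mu,
         laa_log_mu = log(2.5),
         laa_log_sd = (log(4.3) - log(1.3)) / (2 * Z75),
         fev1_l_mean = 3.45, fev1_l_sd = 0.76,
         fev1_fvc_mean = 70.0, fev1_fvc_sd = 10.7,
         lung_volume_mean = 6.5, lung_volume_sd = 1.4),
    class = "cohort_params"
  )
}

qlogis_safe <- function(p) log(p / (1 - p))

#' Simulate a heavy-smoker cohort
#'
#' Draws (log-AWT, Perc15) bivariate normal with the configured
#' correlation, generates FEV1%predicted from the linear structural
#' model plus Gaussian residual, respiratory symptoms from per-symptom
#' logistic models on log-AWT, and %LAA-950 as a fixed monotone
#' (log-linear, decreasing) transform of Perc15. FEV1 in liters,
#' FEV1/FVC and CT lung volume are descriptive transforms calibrated to
#' the cohort means. Deterministic under the seed.
#'
#' @param params A `cohort_params` list, see [default_params()].
#' @return Data.frame with one row per subject (see field list in the
#'   package vignette).
#' @export
simulate_cohort <- function(params = default_params()) {
  p <- params
  if (p$n < 10) stop_domain("n must be at least 10")
  with_seed(p$seed, {
    n <- p$n
    age <- rnorm(n, p$age_mean, p$age_sd)
    pack_years <- exp(rnorm(n, p$packyears_log_mu, p$packyears_log_sd))
    current_smoking <- runif(n) < p$current_smoking_prob
    z1 <- rnorm(n)
    z2 <- p$rho_awt_perc15 * z1 + sqrt(1 - p$rho_awt_perc15^2) * rnorm(n)
    log_awt <- p$awt_log_mu + p$awt_log_sd * z1
    perc15 <- p$perc15_mu + p$perc15_sd * z2
    fev1_pct <- p$beta0 + p$beta_logawt * log_awt + p$beta_perc15 * perc15 +
      rnorm(n, 0, p$resid_sd)
    symptoms <- lapply(names(p$symptom_slopes), function(sym) {
      eta <- p$symptom_intercepts[[sym]] + p$symptom_slopes[[sym]] * log_awt
      runif(n) < plogis(eta)
    })
    names(symptoms) <- names(p$symptom_slopes)
    ## %LAA-950: fixed monotone decreasing map of Perc15 (log-linear)
    log_laa <- p$laa_log_mu - p$laa_log_sd * (perc15 - p$perc15_mu) /
      p$perc15_sd
    laa950_pct <- clamp(exp(log_laa), 0, 100)
    ## descriptive spirometry/volume transforms
    b_fev <- p$fev1_l_mean / 98.2 * 19.7  # slope in L per SD of %pred
    s_extra <- sqrt(max(p$fev1_l_sd^2 - b_fev^2, 0.01))
    zf <- (fev1_pct - 98.2) / 19.7
    fev1_l <- pmax(p$fev1_l_mean + b_fev * zf + rnorm(n, 0, s_extra), 0.3)
    fev1_fvc <- p$fev1_fvc_mean +
      p$fev1_fvc_sd * (0.7 * zf + sqrt(1 - 0.49) * rnorm(n))
    lung_volume_l <- pmax(rnorm(n, p$lung_volume_mean, p$lung_volume_sd), 2)
    data.frame(
      subject_id = seq_len(n), age = age, pack_years = pack_years,
      current_smoking = current_smoking,
      cmh = symptoms$cmh, cough = symptoms$cough,
      dyspnea = symptoms$dyspnea, wheezing = symptoms$wheezing,
      awt35_mm = exp(log_awt), log_awt35 = log_awt,
      perc15_hu = perc15, laa950_pct = laa950_pct,
      lung_volume_l = lung_volume_l, fev1_l = fev1_l,
      fev1_pct_pred = fev1_pct, fev1_fvc_pct = fev1_fvc
    )
  })
}
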