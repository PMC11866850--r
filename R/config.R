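#' Moment-matched parameters for a zero-truncated normal
#'
#' Finds the location and scale of an underlying normal distribution such
#' that, after truncation to `[0, Inf)`, the distribution has the requested
#' mean and standard deviation. Used so that activity exposures drawn on the
#' non-negative scale reproduce published cohort means and SDs exactly in
#' expectation, even when (as for MVPA) a substantial mass of the untruncated
#' normal would fall below zero.
#'
#' @param mean,sd Target mean and standard deviation of the truncated
#'   distribution. Both must be positive.
#' @return A list with elements `mu` and `sigma` (untruncated parameters) and
#'   `alpha = -mu/sigma` (standardised truncation point).
#' @examples
#' p <- truncnorm_params(0.517, 0.447)
#' # moments of the truncated distribution recover the targets
#' @export
truncnorm_params <- function(mean, sd) {
  stopifnot(is.numeric(mean), is.numeric(sd), mean > 0, sd > 0)
  moments <- function(mu, sigma) {
    a <- -mu / sigma
    lam <- dnorm(a) / (1 - pnorm(a))
    m <- mu + sigma * lam
    v <- sigma^2 * (1 - lam * (lam - a))
    c(m, sqrt(pmax(v, 1e-12)))
  }
  obj <- function(par) {
    mm <- moments(par[1], exp(par[2]))
    (mm[1] - mean)^2 + (mm[2] - sd)^2
  }
  fit <- optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  mu <- fit$par[1]
  sigma <- exp(fit$par[2])
  list(mu = mu, sigma = sigma, alpha = -mu / sigma)
}

#' Quantile function of a zero-truncated normal
#'
#' @param p Probabilities in `[0, 1]`.
#' @param pars A list from [truncnorm_params()].
#' @return Quantiles on the original scale, all `>= 0`.
#' @keywords internal
qtruncnorm0 <- function(p, pars) {
  p0 <- pnorm(pars$alpha)
  pmax(0, pars$mu + pars$sigma * qnorm(p0 + p * (1 - p0)))
}

default_exposure_corr <- function() {
  r <- diag(4)
  dimnames(r) <- list(c("tvpa", "mvpa", "lpa", "st"),
                      c("tvpa", "mvpa", "lpa", "st"))
  r["tvpa", "mvpa"] <- r["mvpa", "tvpa"] <- 0.70
  r["tvpa", "lpa"]  <- r["lpa", "tvpa"]  <- 0.60
  r["tvpa", "st"]   <- r["st", "tvpa"]   <- -0.40
  r["mvpa", "lpa"]  <- r["lpa", "mvpa"]  <- 0.30
  r["mvpa", "st"]   <- r["st", "mvpa"]   <- -0.25
  r["lpa", "st"]    <- r["st", "lpa"]    <- -0.35
  r
}

default_covariate_prevalences <- function() {
  norm1 <- function(x) x / sum(x)
  list(
    bmi_cat = norm1(c(under_25 = 0.399, bmi_25_29 = 0.409, bmi_30_plus = 0.191)),
    ethnicity = norm1(c(white = 0.973, other = 0.027)),
    education = norm1(c(degree = 0.448, secondary = 0.367,
                        primary = 0.079, professional = 0.106)),
    employment = norm1(c(employed = 0.540, retired = 0.409, inactive = 0.051)),
    income = norm1(c(lt_18k = 0.159, from_18k = 0.251, from_31k = 0.278,
                     from_52k = 0.233, gt_100k = 0.079)),
    smoking = norm1(c(never = 0.576, previous = 0.363, current = 0.062)),
    alcohol = norm1(c(three_plus_wk = 0.485, lt_three_wk = 0.456, never = 0.060)),
    sleep_duration = norm1(c(h7_8 = 0.714, lt7 = 0.219, gt8 = 0.067)),
    diet_score = norm1(c(s0_2 = 0.346, s3_5 = 0.608, s6_plus = 0.045)),
    famhx_diabetes = c(yes = 0.223),
    famhx_cvd = c(yes = 0.776),
    famhx_cancer = c(yes = 0.375),
    season = norm1(c(autumn = 0.297, spring = 0.228, summer = 0.264, winter = 0.212)),
    assessment_centre = setNames(rep(1 / 22, 22), sprintf("centre_%02d", 1:22))
  )
}

#' Joint FI-by-tertile group labels
#'
#' The nine mutually exclusive analysis groups, frailty category crossed with
#' exposure tertile, ordered with the reference group (robust, tertile 1)
#' first.
#'
#' @return Character vector of length 9.
#' @export
joint_group_levels <- function() {
  as.vector(outer(c("T1", "T2", "T3"), c("robust", "pre_frail", "frail"),
                  function(t, f) paste(f, t, sep = "_")))
}

default_true_log_hr <- function() {
  hr <- c(
    robust_T1 = 1.00, robust_T2 = 0.75, robust_T3 = 0.60,
    pre_frail_T1 = 1.40, pre_frail_T2 = 1.05, pre_frail_T3 = 0.85,
    frail_T1 = 3.00, frail_T2 = 2.00, frail_T3 = 1.50
  )
  log(hr)[joint_group_levels()]
}

default_missing_rates <- function() {
  c(bmi_cat = 0.010, ethnicity = 0.005, education = 0.010, employment = 0.005,
    income = 0.080, townsend = 0.002, smoking = 0.004, alcohol = 0.004,
    sleep_duration = 0.003, diet_score = 0.060)
}

#' Configuration for the synthetic cohort generator
#'
#' Builds a validated configuration for [generate_cohort()]. The defaults
#' describe the emulated study: 78,508 participants aged 45+ wearing a wrist
#' accelerometer for seven consecutive days, intensity-specific exposures with
#' published cohort means/SDs, 49 age-correlated health deficits, ~2.9% deaths
#' over a median ~6.9 years of follow-up, and plausible covariate mixes.
#'
#' @param n_participants Number of participants.
#' @param seed Integer seed governing all randomness of the generator.
#' @param prop_women Proportion of women.
#' @param age_mean,age_sd Mean and SD of age at accelerometer wear (years);
#'   ages are truncated to `[45, 80]`.
#' @param exposure_means,exposure_sds Named numeric vectors over
#'   `tvpa` (mg), `mvpa`, `lpa`, `st` (hours/day): target means and SDs of the
#'   zero-truncated exposure distributions.
#' @param exposure_corr 4x4 positive semi-definite correlation matrix of the
#'   latent Gaussian copula over the four exposures.
#' @param deficit_loadings Numeric vector of length 49: per-item loading on
#'   the latent frailty liability.
#' @param covariate_prevalences Named list of category probability vectors for
#'   the adjustment covariates.
#' @param gompertz_shape Gompertz log-hazard slope in attained age (1/years);
#'   the default doubles the hazard roughly every 8 years.
#' @param gompertz_rate_at_50 Baseline hazard at age 50 (events/person-year)
#'   for the reference group. `NULL` (default) solves the level at generation
#'   time so the expected death fraction equals `target_death_fraction`.
#' @param target_death_fraction Expected proportion of deaths used to
#'   calibrate the baseline when `gompertz_rate_at_50` is `NULL`.
#' @param true_log_hr Named vector of true log hazard ratios, one per joint
#'   FI-by-tertile group (see [joint_group_levels()]); the reference group
#'   `robust_T1` must be 0.
#' @param sex_log_hr True additional log hazard for men.
#' @param recruit_window_years Length of the accrual window (years); entry is
#'   uniform over the window.
#' @param admin_censor_years Time from the start of the accrual window to the
#'   administrative censoring date (years).
#' @param dropout_rate Exponential loss-to-follow-up rate (1/years).
#' @param missing_rates Named vector of per-covariate missingness fractions
#'   used by [inject_missingness()] when called by the pipeline.
#' @param wear_day_probs Named numeric vector: probability of recording 3..7
#'   complete wear days (names `"3"`..`"7"`).
#' @param liability_tvpa_cor Correlation between the latent frailty liability
#'   and (minus) the latent TVPA score, inducing lower activity in frailer
#'   participants.
#' @param deficit_logit_shift Additive shift on every deficit-item intercept
#'   (logit scale); raises or lowers overall frailty prevalence.
#' @param deficit_age_slope Per-year log-odds increase of each deficit.
#' @param deficit_missing_rate Fraction of participants with one deficit item
#'   missing (exercises the complete-FI exclusion rule).
#' @param shift_worker_prop Proportion flagged as shift workers (sensitivity
#'   exclusions only).
#' @param awake_window Default awake window as `"HH:MM-HH:MM"`.
#' @param enmo_noise_sdlog Log-scale SD of the multiplicative epoch-level
#'   ENMO noise.
#' @param n_epoch_participants Number of participants (taken from id 1
#'   upwards) for which [generate_cohort()] materialises epoch records;
#'   epochs for any subset can always be produced later with
#'   [generate_epochs()].
#'
#' @return A list of class `frailpa_config`.
#' @examples
#' cfg <- cohort_config(n_participants = 500, seed = 1)
#' @export
cohort_config <- function(n_participants = 78508,
                          seed = 2025L,
                          prop_women = 0.555,
                          age_mean = 62.0,
                          age_sd = 7.8,
                          exposure_means = c(tvpa = 38.4, mvpa = 0.517,
                                             lpa = 5.27, st = 7.98),
                          exposure_sds = c(tvpa = 11.9, mvpa = 0.447,
                                           lpa = 1.58, st = 1.60),
                          exposure_corr = default_exposure_corr(),
                          deficit_loadings = NULL,
                          covariate_prevalences = default_covariate_prevalences(),
                          gompertz_shape = log(2) / 8,
                          gompertz_rate_at_50 = NULL,
                          target_death_fraction = 0.029,
                          true_log_hr = default_true_log_hr(),
                          sex_log_hr = 0.40,
                          recruit_window_years = 2.9,
                          admin_censor_years = 8.35,
                          dropout_rate = 0.002,
                          missing_rates = default_missing_rates(),
                          wear_day_probs = c(`3` = 0.01, `4` = 0.02, `5` = 0.05,
                                             `6` = 0.12, `7` = 0.80),
                          liability_tvpa_cor = 0.35,
                          deficit_logit_shift = 0,
                          deficit_age_slope = 0.035,
                          deficit_missing_rate = 0,
                          shift_worker_prop = 0.037,
                          awake_window = "06:00-22:00",
                          enmo_noise_sdlog = 0.5,
                          n_epoch_participants = NULL) {
  if (is.null(deficit_loadings)) {
    # fixed, evenly spread loadings over the 49 default codebook items
    deficit_loadings <- seq(0.3, 0.7, length.out = 49)
  }
  cfg <- list(
    n_participants = as.integer(n_participants), seed = as.integer(seed),
    prop_women = prop_women, age_mean = age_mean, age_sd = age_sd,
    exposure_means = exposure_means, exposure_sds = exposure_sds,
    exposure_corr = exposure_corr, deficit_loadings = deficit_loadings,
    covariate_prevalences = covariate_prevalences,
    gompertz_shape = gompertz_shape, gompertz_rate_at_50 = gompertz_rate_at_50,
    target_death_fraction = target_death_fraction, true_log_hr = true_log_hr,
    sex_log_hr = sex_log_hr, recruit_window_years = recruit_window_years,
    admin_censor_years = admin_censor_years, dropout_rate = dropout_rate,
    missing_rates = missing_rates, wear_day_probs = wear_day_probs,
    liability_tvpa_cor = liability_tvpa_cor,
    deficit_logit_shift = deficit_logit_shift,
    deficit_age_slope = deficit_age_slope,
    deficit_missing_rate = deficit_missing_rate,
    shift_worker_prop = shift_worker_prop,
    awake_window = awake_window, enmo_noise_sdlog = enmo_noise_sdlog,
    n_epoch_participants = n_epoch_participants %||%
      min(as.integer(n_participants), 1000L)
  )
  class(cfg) <- "frailpa_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (is.na(cfg$n_participants) || cfg$n_participants < 1) {
    abort("`n_participants` must be a positive integer.",
          class = "frailpa_config_error")
  }
  fracs <- c(prop_women = cfg$prop_women, cfg$missing_rates,
             deficit_missing_rate = cfg$deficit_missing_rate,
             shift_worker_prop = cfg$shift_worker_prop)
  if (any(fracs < 0 | fracs > 1)) {
    abort("All proportions and missing rates must lie in [0, 1].",
          class = "frailpa_config_error")
  }
  if (any(cfg$exposure_sds <= 0) || cfg$age_sd <= 0) {
    abort("Standard deviations must be positive.",
          class = "frailpa_config_error")
  }
  r <- cfg$exposure_corr
  if (!is.matrix(r) || nrow(r) != 4 || ncol(r) != 4 ||
      any(abs(r - t(r)) > 1e-10)) {
    abort("`exposure_corr` must be a symmetric 4x4 matrix.",
          class = "frailpa_config_error")
  }
  if (min(eigen(r, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
    abort("`exposure_corr` is not positive semi-definite.",
          class = "frailpa_config_error")
  }
  lv <- joint_group_levels()
  if (!all(lv %in% names(cfg$true_log_hr))) {
    abort("`true_log_hr` must name all nine joint groups.",
          class = "frailpa_config_error")
  }
  if (abs(cfg$true_log_hr[["robust_T1"]]) > 0) {
    abort("`true_log_hr` must be 0 for the reference group `robust_T1`.",
          class = "frailpa_config_error")
  }
  if (cfg$gompertz_shape <= 0) {
    abort("`gompertz_shape` must be positive.", class = "frailpa_config_error")
  }
  if (abs(sum(cfg$wear_day_probs) - 1) > 1e-8) {
    abort("`wear_day_probs` must sum to 1.", class = "frailpa_config_error")
  }
  invisible(cfg)
}
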