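#' Simulate survival times from a Gompertz proportional-hazards model
#'
#' Event times are drawn by inverse-transform sampling from a Gompertz
#' hazard in attained age, `h(t) = rate_at_50 * exp(shape * (age - 50 + t))`,
#' scaled multiplicatively by `exp(linear_predictor)`. Censoring is the
#' earlier of an administrative horizon and exponential loss to follow-up.
#'
#' @param linear_predictor Numeric vector of per-participant log hazard
#'   ratios; must be finite.
#' @param baseline List with `shape` (1/years, > 0), `rate_at_50`
#'   (events/person-year) and `age` (age in years at the start of follow-up;
#'   scalar or vector).
#' @param censoring List with `horizon_years` (administrative censoring time,
#'   scalar or vector; may be 0) and optional `dropout_rate` (1/years,
#'   default 0).
#' @return A tibble with `time_years` (exact), `time_months` (person-time in
#'   whole months, the analysis timescale) and logical `event`.
#' @examples
#' set.seed(1)
#' simulate_survival(rep(0, 5),
#'                   baseline = list(shape = 0.087, rate_at_50 = 0.01, age = 60),
#'                   censoring = list(horizon_years = 8))
#' @export
simulate_survival <- function(linear_predictor, baseline, censoring) {
  if (any(!is.finite(linear_predictor))) {
    abort("`linear_predictor` must be finite.", class = "frailpa_sim_error")
  }
  g <- baseline$shape
  b0 <- baseline$rate_at_50
  if (is.null(g) || g <= 0) {
    abort("`baseline$shape` must be positive.", class = "frailpa_sim_error")
  }
  if (is.null(b0) || b0 <= 0) {
    abort("`baseline$rate_at_50` must be positive.", class = "frailpa_sim_error")
  }
  n <- length(linear_predictor)
  age <- rep_len(baseline$age %||% 50, n)
  horizon <- rep_len(censoring$horizon_years, n)
  dropout <- censoring$dropout_rate %||% 0

  # H(t) = (b0/g) e^{g(age-50)} (e^{gt}-1) e^{lp};  T = H^{-1}(E), E ~ Exp(1)
  a <- b0 / g * exp(g * (age - 50) + linear_predictor)
  e <- rexp(n)
  t_event <- log1p(e / a) / g
  t_cens <- pmax(0, horizon)
  if (dropout > 0) t_cens <- pmin(t_cens, rexp(n, rate = dropout))
  event <- t_event <= t_cens
  t_obs <- pmin(t_event, t_cens)
  tibble(
    time_years = t_obs,
    time_months = as.integer(pmax(ceiling(12 * t_obs), ifelse(t_obs > 0, 1, 0))),
    event = event
  )
}

# Solve the Gompertz level so the expected death fraction over the realized
# ages, linear predictors and censoring horizons equals the target.
calibrate_rate_at_50 <- function(target, shape, age, lp, horizon) {
  expected <- function(b0) {
    h <- b0 / shape * exp(shape * (age - 50) + lp) * expm1(shape * horizon)
    mean(-expm1(-h))
  }
  uniroot(function(lb0) expected(10^lb0) - target,
          lower = -9, upper = -0.3, tol = 1e-12)$root |>
    (\(x) 10^x)()
}

draw_categorical <- function(n, probs) {
  factor(sample(names(probs), n, replace = TRUE, prob = probs),
         levels = names(probs))
}

draw_deficit_responses <- function(codebook, eta) {
  # eta: participants x items linear predictor on the logit scale
  n <- nrow(eta)
  out <- vector("list", nrow(codebook))
  names(out) <- paste0("def_", codebook$item)
  for (j in seq_len(nrow(codebook))) {
    levs <- codebook$levels[[j]]
    k <- length(levs)
    latent <- eta[, j] + rlogis_n(n)
    if (k == 2) {
      out[[j]] <- factor(ifelse(latent > 0, levs[2], levs[1]), levels = levs)
    } else {
      # graded severity: fixed thresholds 0, 1.1, 2.2, ... above the binary cut
      th <- c(-Inf, 0 + 1.1 * (0:(k - 2)), Inf)
      out[[j]] <- factor(levs[findInterval(latent, th)], levels = levs)
    }
  }
  as_tibble(out)
}

rlogis_n <- function(n) stats::rlogis(n)

#' Generate a synthetic accelerometer-frailty cohort
#'
#' Draws a complete cohort with known ground truth: correlated non-negative
#' activity exposures (Gaussian copula with zero-truncated normal marginals,
#' MVPA + LPA + ST capped at the 16-h awake window), 49 deficit-item
#' responses driven by a latent frailty liability correlated with low
#' activity and with age, Table-1-style covariates, and Gompertz
#' proportional-hazards survival with administrative censoring over a
#' multi-year accrual window. Epoch-level records are materialised for the
#' first `config$n_epoch_participants` participants and can be regenerated
#' for any subset with [generate_epochs()].
#'
#' @param config A [cohort_config()] object.
#' @param epochs Logical; materialise epoch records for the configured subset
#'   (default `TRUE`). Setting `FALSE` skips epoch emission entirely.
#' @return A list with elements `cohort` (tibble, one row per participant),
#'   `epochs` (long tibble of 30-s epoch records, or `NULL`) and `truth`
#'   (list with per-participant `effects`, the `baseline` hazard parameters
#'   and the injected `true_log_hr` map).
#' @examples
#' sim <- generate_cohort(cohort_config(n_participants = 200, seed = 7,
#'                                      n_epoch_participants = 2))
#' @export
generate_cohort <- function(config, epochs = TRUE) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_participants
  ids <- seq_len(n)

  sex <- factor(ifelse(runif(n) < config$prop_women, "women", "men"),
                levels = c("women", "men"))
  # age truncated to [45, 80]
  plo <- pnorm(45, config$age_mean, config$age_sd)
  phi <- pnorm(80, config$age_mean, config$age_sd)
  age <- qnorm(runif(n, plo, phi), config$age_mean, config$age_sd)

  # correlated exposures through a Gaussian copula
  ch <- chol(config$exposure_corr)
  z <- matrix(rnorm(n * 4), n, 4) %*% ch
  colnames(z) <- colnames(config$exposure_corr)
  pars <- purrr::map(c("tvpa", "mvpa", "lpa", "st"), function(e) {
    truncnorm_params(config$exposure_means[[e]], config$exposure_sds[[e]])
  })
  names(pars) <- c("tvpa", "mvpa", "lpa", "st")
  tvpa <- qtruncnorm0(pnorm(z[, "tvpa"]), pars$tvpa)
  mvpa <- qtruncnorm0(pnorm(z[, "mvpa"]), pars$mvpa)
  lpa <- qtruncnorm0(pnorm(z[, "lpa"]), pars$lpa)
  st <- qtruncnorm0(pnorm(z[, "st"]), pars$st)

  awake_h <- awake_window_hours(config$awake_window)
  over <- mvpa + lpa + st > awake_h
  st[over] <- pmax(0, awake_h - mvpa[over] - lpa[over])
  too_active <- mvpa + lpa > awake_h
  if (any(too_active)) {
    sc <- awake_h / (mvpa[too_active] + lpa[too_active])
    mvpa[too_active] <- mvpa[too_active] * sc
    lpa[too_active] <- lpa[too_active] * sc
    st[too_active] <- 0
  }
  # quantize behaviour hours to whole 30-s epochs so epoch emission is exact
  epd <- as.integer(round(awake_h * 120))
  n_mvpa <- as.integer(round(mvpa * 120))
  n_lpa <- as.integer(round(lpa * 120))
  n_st <- pmin(as.integer(round(st * 120)), epd - n_mvpa - n_lpa)
  mvpa_q <- n_mvpa / 120
  lpa_q <- n_lpa / 120
  st_q <- n_st / 120

  # wear schedule: consecutive days from a random start weekday
  n_wear <- as.integer(sample(names(config$wear_day_probs), n, replace = TRUE,
                              prob = config$wear_day_probs))
  start_wd <- sample.int(7, n, replace = TRUE)
  weekend_covered <- map_lgl(seq_len(n), function(i) {
    any(((start_wd[i] + seq_len(n_wear[i]) - 2) %% 7) + 1 >= 6)
  })
  valid_wear <- n_wear >= 3 & weekend_covered

  # latent frailty liability, lower activity in frailer participants
  rho <- config$liability_tvpa_cor
  liability <- -rho * z[, "tvpa"] + sqrt(1 - rho^2) * rnorm(n)

  codebook <- default_deficit_codebook()
  intercepts <- deficit_intercepts() + config$deficit_logit_shift
  eta <- outer(rep(1, n), intercepts) +
    outer(liability, config$deficit_loadings) +
    config$deficit_age_slope * (age - 62)
  responses <- draw_deficit_responses(codebook, eta)

  scores <- code_deficits(responses, codebook)
  fi_tab <- compute_fi(scores)

  # knock out one random item for a small fraction (exercises exclusion rule)
  if (config$deficit_missing_rate > 0) {
    hit <- runif(n) < config$deficit_missing_rate
    if (any(hit)) {
      which_item <- sample.int(nrow(codebook), sum(hit), replace = TRUE)
      for (j in unique(which_item)) {
        rows <- which(hit)[which_item == j]
        responses[[j]][rows] <- NA
      }
    }
  }

  tert <- assign_tertiles(tvpa)
  joint_group <- factor(paste(as.character(fi_tab$fi_category),
                              as.character(tert$labels), sep = "_"),
                        levels = joint_group_levels())
  lp <- unname(config$true_log_hr[as.character(joint_group)]) +
    config$sex_log_hr * (sex == "men")

  entry <- runif(n, 0, config$recruit_window_years)
  horizon <- config$admin_censor_years - entry
  b0 <- config$gompertz_rate_at_50 %||%
    calibrate_rate_at_50(config$target_death_fraction, config$gompertz_shape,
                         age, lp, horizon)
  surv <- simulate_survival(lp,
                            baseline = list(shape = config$gompertz_shape,
                                            rate_at_50 = b0, age = age),
                            censoring = list(horizon_years = horizon,
                                             dropout_rate = config$dropout_rate))

  cp <- config$covariate_prevalences
  cohort <- tibble(
    participant_id = ids,
    sex = sex,
    age_accel = age,
    tvpa_mg = tvpa,
    mvpa_h_day = mvpa_q,
    lpa_h_day = lpa_q,
    st_h_day = st_q,
    n_valid_days = n_wear,
    wear_start_weekday = start_wd,
    weekend_covered = weekend_covered,
    valid_wear = valid_wear,
    wear_days = n_wear,
    assessment_centre = draw_categorical(n, cp$assessment_centre),
    bmi_cat = draw_categorical(n, cp$bmi_cat),
    ethnicity = draw_categorical(n, cp$ethnicity),
    education = draw_categorical(n, cp$education),
    employment = draw_categorical(n, cp$employment),
    income = draw_categorical(n, cp$income),
    townsend = rnorm(n, -1.79, 2.78),
    smoking = draw_categorical(n, cp$smoking),
    alcohol = draw_categorical(n, cp$alcohol),
    sleep_duration = draw_categorical(n, cp$sleep_duration),
    diet_score = draw_categorical(n, cp$diet_score),
    famhx_diabetes = factor(ifelse(runif(n) < cp$famhx_diabetes[["yes"]],
                                   "yes", "no"), levels = c("no", "yes")),
    famhx_cvd = factor(ifelse(runif(n) < cp$famhx_cvd[["yes"]], "yes", "no"),
                       levels = c("no", "yes")),
    famhx_cancer = factor(ifelse(runif(n) < cp$famhx_cancer[["yes"]],
                                 "yes", "no"), levels = c("no", "yes")),
    season = draw_categorical(n, cp$season),
    shift_worker = runif(n) < config$shift_worker_prop,
    time_years = surv$time_years,
    time_months = surv$time_months,
    event = surv$event
  )
  cohort <- bind_cols(cohort, responses)
  cohort <- cohort |>
    mutate(fi = fi_tab$fi, fi_category = fi_tab$fi_category,
           fi_complete = !purrr::reduce(purrr::map(responses, is.na), `|`))

  truth <- list(
    effects = tibble(participant_id = ids, liability = liability,
                     joint_group = joint_group, tvpa_tertile = tert$labels,
                     linear_predictor = lp),
    baseline = list(shape = config$gompertz_shape, rate_at_50 = b0),
    true_log_hr = config$true_log_hr,
    tertile_cuts = tert$scheme
  )

  ep <- NULL
  if (epochs && config$n_epoch_participants > 0) {
    ep <- generate_epochs(cohort, config,
                          ids = seq_len(min(n, config$n_epoch_participants)))
  }
  list(cohort = cohort, epochs = ep, truth = truth)
}

# Fixed item intercepts (logit scale): evenly spread so items range from
# common to rare, overall level set for a right-skewed FI with a few percent
# frail at the default liability and age mix.
deficit_intercepts <- function() {
  -2.30 + 0.8 * qnorm(stats::ppoints(49))
}

#' Inject missing-completely-at-random covariate values
#'
#' Masks covariate values at the requested per-column rates. Outcome,
#' follow-up, deficit-item and exposure-summary columns are protected and
#' requesting a rate on them is an error.
#'
#' @param cohort Cohort tibble.
#' @param missing_rates Named numeric vector of rates in `[0, 1]`; names are
#'   covariate columns.
#' @param seed Integer seed.
#' @return The cohort with `NA`s injected.
#' @export
inject_missingness <- function(cohort, missing_rates, seed = 1L) {
  if (any(missing_rates < 0 | missing_rates > 1)) {
    abort("Missing rates must lie in [0, 1].", class = "frailpa_missing_error")
  }
  protected <- c("participant_id", "time_years", "time_months", "event",
                 "tvpa_mg", "mvpa_h_day", "lpa_h_day", "st_h_day",
                 "fi", "fi_category", "fi_complete",
                 grep("^def_", names(cohort), value = TRUE))
  bad <- intersect(names(missing_rates), protected)
  if (length(bad)) {
    abort(paste0("Missingness requested on protected column(s): ",
                 paste(bad, collapse = ", ")),
          class = "frailpa_missing_error")
  }
  unknown <- setdiff(names(missing_rates), names(cohort))
  if (length(unknown)) {
    abort(paste0("Unknown column(s): ", paste(unknown, collapse = ", ")),
          class = "frailpa_missing_error")
  }
  set.seed(seed)
  for (col in names(missing_rates)) {
    r <- missing_rates[[col]]
    if (r > 0) cohort[[col]][runif(nrow(cohort)) < r] <- NA
  }
  cohort
}
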