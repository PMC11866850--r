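# Shared fixtures: small generator configs, hand-built epoch tables, and
# group-structured survival simulations with known truth.

small_config <- function(n = 400, seed = 101, ...) {
  args <- list(...)
  if (is.null(args$n_epoch_participants)) args$n_epoch_participants <- 0
  do.call(cohort_config,
          c(list(n_participants = n, seed = seed), args))
}

# Build a full-coverage epoch day: 2880 30-s epochs with a given behaviour
# layout inside the 06:00-22:00 window.
make_day <- function(participant_id, day_index, weekday,
                     n_mvpa = 60, n_light = 600, n_sed = 960,
                     enmo = 40, coverage = 1) {
  all_secs <- seq(0L, 86370L, by = 30L)
  awake <- all_secs >= 21600 & all_secs < 79200
  beh <- rep("sleep", length(all_secs))
  idx <- which(awake)
  beh[idx[seq_len(n_mvpa)]] <- "mvpa"
  beh[idx[n_mvpa + seq_len(n_light)]] <- "light"
  beh[idx[n_mvpa + n_light + seq_len(n_sed)]] <- "sedentary"
  keep <- seq_len(floor(length(all_secs) * coverage))
  tibble::tibble(
    participant_id = participant_id, day_index = day_index,
    weekday = factor(weekday, levels = weekday_levels()),
    epoch_start = all_secs[keep],
    enmo_mg = rep(enmo, length(all_secs))[keep],
    behavior = factor(beh, levels = c("sleep", "sedentary", "light",
                                      "mvpa"))[keep]
  )
}

make_week <- function(participant_id, weekdays = weekday_levels(), ...) {
  dplyr::bind_rows(lapply(seq_along(weekdays), function(i) {
    make_day(participant_id, i, weekdays[i], ...)
  }))
}

# Hand-written Cox partial log-likelihood for one covariate, no ties:
# the independent oracle used against fit_cox.
partial_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Survival simulation over nine labelled groups with injected log HRs.
sim_group_cohort <- function(n, log_hr = stats::setNames(rep(0, 9),
                                                         joint_group_levels()),
                             prev = rep(1 / 9, 9), rate_at_50 = 0.012,
                             shape = log(2) / 8, horizon = 7, seed = 1) {
  set.seed(seed)
  g <- sample(names(log_hr), n, replace = TRUE, prob = prev)
  age <- runif(n, 50, 75)
  sex <- factor(sample(c("women", "men"), n, TRUE),
                levels = c("women", "men"))
  surv <- simulate_survival(
    unname(log_hr[g]),
    baseline = list(shape = shape, rate_at_50 = rate_at_50, age = age),
    censoring = list(horizon_years = horizon))
  tibble::tibble(
    participant_id = seq_len(n),
    joint_group = factor(g, levels = joint_group_levels()),
    fi_category = factor(sub("_T[123]$", "", g),
                         levels = c("robust", "pre_frail", "frail")),
    tvpa_tertile = factor(sub("^.*_(T[123])$", "\\1", g),
                          levels = c("T1", "T2", "T3")),
    age_accel = age, sex = sex,
    time_years = surv$time_years, time_months = surv$time_months,
    event = surv$event
  )
}

# Continuous-exposure survival simulation with a log-linear effect.
sim_loglinear_cohort <- function(n, beta = 0.02, x_mean = 38, x_sd = 12,
                                 rate_at_50 = 0.01, seed = 1) {
  set.seed(seed)
  x <- rnorm(n, x_mean, x_sd)
  age <- runif(n, 50, 75)
  surv <- simulate_survival(
    beta * (x - x_mean),
    baseline = list(shape = log(2) / 8, rate_at_50 = rate_at_50, age = age),
    censoring = list(horizon_years = 7))
  tibble::tibble(participant_id = seq_len(n), tvpa_mg = x, age_accel = age,
                 time_months = surv$time_months, event = surv$event)
}

default_pop <- function() synthetic_population_rates()
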