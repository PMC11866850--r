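test_that("identical config and seed reproduce the cohort and epochs exactly", {
  cfg <- small_config(n = 120, seed = 77, n_epoch_participants = 6)
  s1 <- generate_cohort(cfg)
  s2 <- generate_cohort(cfg)
  expect_identical(s1$cohort, s2$cohort)
  expect_identical(s1$epochs, s2$epochs)
  expect_identical(s1$truth$effects, s2$truth$effects)
})

test_that("configuration errors are caught", {
  bad_corr <- default_exposure_corr()
  bad_corr[1, 2] <- bad_corr[2, 1] <- 0.999
  bad_corr[1, 3] <- bad_corr[3, 1] <- -0.999
  bad_corr[2, 3] <- bad_corr[3, 2] <- 0.999
  expect_error(cohort_config(exposure_corr = bad_corr),
               class = "frailpa_config_error")
  expect_error(cohort_config(n_participants = 0),
               class = "frailpa_config_error")
  expect_error(cohort_config(true_log_hr = c(robust_T1 = 0.5)),
               class = "frailpa_config_error")
  expect_error(cohort_config(prop_women = 1.4),
               class = "frailpa_config_error")
})

test_that("zero-truncated marginals match their target moments", {
  for (tg in list(c(0.517, 0.447), c(38.4, 11.9), c(7.98, 1.6))) {
    p <- truncnorm_params(tg[1], tg[2])
    set.seed(4)
    x <- qtruncnorm0(runif(2e5), p)
    expect_equal(mean(x), tg[1], tolerance = 0.01)
    expect_equal(sd(x), tg[2], tolerance = 0.01)
    expect_true(all(x >= 0))
  }
})

test_that("survival simulation reduces to the exponential in the flat limit", {
  set.seed(11)
  n <- 40000
  s <- simulate_survival(rep(0, n),
                         baseline = list(shape = 1e-9, rate_at_50 = 0.05,
                                         age = 50),
                         censoring = list(horizon_years = Inf))
  expect_true(all(s$event))
  expect_equal(1 / mean(s$time_years), 0.05, tolerance = 0.03)
})

test_that("a log-2 linear predictor doubles the cumulative hazard", {
  set.seed(21)
  n <- 30000
  base <- list(shape = log(2) / 8, rate_at_50 = 0.02, age = 60)
  cens <- list(horizon_years = 8)
  s0 <- simulate_survival(rep(0, n), base, cens)
  s1 <- simulate_survival(rep(log(2), n), base, cens)
  na_at <- function(s, t) {
    f <- survival::survfit(survival::Surv(s$time_years, s$event) ~ 1)
    f$cumhaz[max(which(f$time <= t))]
  }
  expect_equal(na_at(s1, 5) / na_at(s0, 5), 2, tolerance = 0.1)
  expect_equal(na_at(s1, 7) / na_at(s0, 7), 2, tolerance = 0.1)
})

test_that("a zero censoring horizon censors everyone at time zero", {
  s <- simulate_survival(rep(0, 50),
                         baseline = list(shape = 0.1, rate_at_50 = 0.01,
                                         age = 50),
                         censoring = list(horizon_years = 0))
  expect_true(all(!s$event))
  expect_true(all(s$time_months == 0))
})

test_that("non-finite linear predictors are rejected", {
  expect_error(simulate_survival(c(0, NA),
                                 baseline = list(shape = 0.1,
                                                 rate_at_50 = 0.01, age = 50),
                                 censoring = list(horizon_years = 1)),
               class = "frailpa_sim_error")
})

test_that("nelson-aalen hazard ratios between injected groups match the truth", {
  lh <- stats::setNames(rep(0, 9), joint_group_levels())
  lh["frail_T1"] <- log(3)
  co <- sim_group_cohort(60000, log_hr = lh, rate_at_50 = 0.02, seed = 5)
  na_at <- function(d, t) {
    f <- survival::survfit(survival::Surv(d$time_years, d$event) ~ 1)
    f$cumhaz[max(which(f$time <= t))]
  }
  r <- na_at(co[co$joint_group == "frail_T1", ], 6) /
    na_at(co[co$joint_group == "robust_T1", ], 6)
  expect_equal(r, 3, tolerance = 0.15)
})

test_that("missingness injection hits the requested rates and protections", {
  cfg <- small_config(n = 10000, seed = 31)
  co <- generate_cohort(cfg, epochs = FALSE)$cohort

  same <- inject_missingness(co, c(income = 0), seed = 2)
  expect_identical(same$income, co$income)

  all_na <- inject_missingness(co, c(income = 1), seed = 2)
  expect_true(all(is.na(all_na$income)))

  m5 <- inject_missingness(co, c(income = 0.05), seed = 2)
  expect_gte(sum(is.na(m5$income)), 450)
  expect_lte(sum(is.na(m5$income)), 550)

  expect_error(inject_missingness(co, c(event = 0.1)),
               class = "frailpa_missing_error")
  expect_error(inject_missingness(co, c(def_diabetes = 0.1)),
               class = "frailpa_missing_error")
})

test_that("aggregating generated epochs reproduces the drawn summaries", {
  cfg <- cohort_config(n_participants = 60, seed = 13,
                       n_epoch_participants = 60)
  sim <- generate_cohort(cfg)
  agg <- aggregate_epochs(sim$epochs)
  co <- sim$cohort[match(agg$participant_id, sim$cohort$participant_id), ]
  expect_equal(agg$tvpa_mg, co$tvpa_mg, tolerance = 1e-10)
  expect_equal(agg$mvpa_h_day, co$mvpa_h_day, tolerance = 1 / 120)
  expect_equal(agg$lpa_h_day, co$lpa_h_day, tolerance = 1 / 120)
  expect_equal(agg$st_h_day, co$st_h_day, tolerance = 1 / 120)
  expect_identical(agg$n_valid_days, co$n_valid_days)
  expect_identical(agg$weekend_covered, co$weekend_covered)
})

test_that("epoch emission is invariant to how participants are chunked", {
  cfg <- cohort_config(n_participants = 600, seed = 17,
                       n_epoch_participants = 0)
  co <- generate_cohort(cfg, epochs = FALSE)$cohort
  a <- summarise_epoch_exposures(co, cfg, ids = 240:320, block_size = 50)
  b <- summarise_epoch_exposures(co, cfg, ids = 240:320, block_size = 500)
  expect_identical(a, b)
})
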