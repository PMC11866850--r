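toy_spec <- function() {
  analysis_spec("tvpa", exposure_form = "continuous", fi_form = "none",
                adjustment = character(), mutual_adjustment = FALSE)
}

test_that("fit_cox matches brute-force partial-likelihood maximisation", {
  toys <- list(
    tibble::tibble(tvpa_mg = c(0.2, 1.1, -0.4, 0.9, -1.3, 0.5),
                   time_months = c(3, 7, 11, 15, 21, 28),
                   event = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE)),
    tibble::tibble(tvpa_mg = c(1, 0, 1, 0, 1, 0, 1, 0),
                   time_months = c(2, 5, 9, 13, 17, 22, 26, 31),
                   event = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE,
                             TRUE, TRUE))
  )
  for (d in toys) {
    fit <- fit_cox(d, toy_spec())
    brute <- stats::optimize(function(b) {
      partial_loglik(b, d$tvpa_mg, d$time_months, d$event)
    }, c(-6, 6), maximum = TRUE, tol = 1e-9)$maximum
    expect_equal(unname(coef(fit)[1]), brute, tolerance = 1e-4)
  }
})

test_that("a true hazard ratio of 2 is recovered on a large simulation", {
  set.seed(61)
  n <- 20000
  x <- rbinom(n, 1, 0.5)
  s <- simulate_survival(log(2) * x,
                         baseline = list(shape = 1e-9, rate_at_50 = 0.03,
                                         age = 50),
                         censoring = list(horizon_years = 7))
  d <- tibble::tibble(tvpa_mg = x, time_months = s$time_months,
                      event = s$event)
  fit <- fit_cox(d, toy_spec())
  expect_equal(unname(coef(fit)[1]), log(2), tolerance = 0.1)
})

test_that("a null exposure gives a near-zero coefficient", {
  set.seed(62)
  n <- 20000
  x <- rnorm(n)
  s <- simulate_survival(rep(0, n),
                         baseline = list(shape = 1e-9, rate_at_50 = 0.03,
                                         age = 50),
                         censoring = list(horizon_years = 7))
  d <- tibble::tibble(tvpa_mg = x, time_months = s$time_months,
                      event = s$event)
  fit <- fit_cox(d, toy_spec())
  z <- coef(fit)[1] / sqrt(vcov(fit)[1, 1])
  expect_lt(abs(z), 3)
})

test_that("exposure hazard ratios are invariant to covariate rescaling", {
  co <- sim_group_cohort(4000, rate_at_50 = 0.02, seed = 63)
  co$townsend <- rnorm(4000)
  spec <- analysis_spec("tvpa", adjustment = c("age_accel", "townsend"))
  f1 <- fit_cox(co, spec)
  co2 <- co
  co2$townsend <- co2$townsend * 1000
  f2 <- fit_cox(co2, spec)
  keep <- grep("tertile", names(coef(f1)))
  expect_equal(coef(f1)[keep], coef(f2)[keep], tolerance = 1e-8)
})

test_that("missing values and event-free levels are refused", {
  co <- sim_group_cohort(500, rate_at_50 = 0.02, seed = 64)
  co$age_accel[3] <- NA
  expect_error(fit_cox(co, analysis_spec("tvpa", adjustment = "age_accel")),
               class = "frailpa_fit_error")
  co2 <- sim_group_cohort(500, rate_at_50 = 0.02, seed = 64)
  co2$event[co2$fi_category == "frail"] <- FALSE
  expect_error(fit_cox(co2, analysis_spec("tvpa", adjustment = character())),
               regexp = "frail",
               class = "frailpa_fit_error")
})

test_that("the joint table has nine rows with an exact unit reference", {
  lh <- default_true_log_hr()
  co <- sim_group_cohort(12000, log_hr = lh, rate_at_50 = 0.02, seed = 65)
  jt <- joint_group_hrs(co, analysis_spec("tvpa",
                                          adjustment = c("age_accel", "sex")))
  expect_equal(nrow(jt), 9)
  expect_equal(jt$group, joint_group_levels())
  ref <- jt[jt$is_reference, ]
  expect_equal(nrow(ref), 1)
  expect_equal(ref$group, "robust_T1")
  expect_equal(c(ref$hr, ref$ci_lo, ref$ci_hi), c(1, 1, 1))
  expect_true(all(jt$ci_lo <= jt$hr & jt$hr <= jt$ci_hi))
  # the strong frail effect is in the right neighbourhood
  expect_equal(jt$hr[jt$group == "frail_T1"], 3, tolerance = 0.35)
})

test_that("an empty or event-free joint group is an explicit error", {
  co <- sim_group_cohort(800, rate_at_50 = 0.02, seed = 66)
  co <- co[co$joint_group != "frail_T3", ]
  expect_error(joint_group_hrs(co, analysis_spec("tvpa",
                                                 adjustment = character())),
               regexp = "frail_T3", class = "frailpa_fit_error")
})

test_that("collapsing the joint model to main effects cannot raise the likelihood", {
  co <- sim_group_cohort(6000, log_hr = default_true_log_hr(),
                         rate_at_50 = 0.02, seed = 67)
  full <- fit_cox(co, analysis_spec("tvpa", fi_form = "joint",
                                    adjustment = "age_accel"))
  main <- fit_cox(co, analysis_spec("tvpa", fi_form = "category",
                                    adjustment = "age_accel"))
  expect_gte(full$loglik, main$loglik - 1e-8)
})

test_that("tidy and glance report the fit in broom shape", {
  co <- sim_group_cohort(2000, rate_at_50 = 0.02, seed = 68)
  fit <- fit_cox(co, analysis_spec("tvpa", adjustment = "age_accel"))
  td <- tidy(fit, exponentiate = TRUE)
  expect_true(all(c("term", "estimate", "conf_low", "conf_high") %in%
                    names(td)))
  expect_true(all(td$estimate > 0))
  gl <- glance(fit)
  expect_equal(gl$n_events, fit$n_events)
})
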