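test_that("the LRT of a model against itself is exactly null", {
  co <- sim_group_cohort(1500, rate_at_50 = 0.03, seed = 81)
  fit <- fit_cox(co, analysis_spec("tvpa", adjustment = "age_accel"))
  out <- lrt_interaction(fit, fit)
  expect_equal(out$lrt_stat, 0)
  expect_equal(out$lrt_df, 0L)
  expect_equal(out$lrt_p, 1)
})

test_that("non-nested fits are refused", {
  co <- sim_group_cohort(1500, rate_at_50 = 0.03, seed = 82)
  f_small <- fit_cox(co, analysis_spec("tvpa", adjustment = character()))
  f_big <- fit_cox(co, analysis_spec("tvpa", adjustment = "age_accel"))
  expect_error(lrt_interaction(f_small, f_big),
               class = "frailpa_lrt_error")
  co2 <- co[1:1000, ]
  f_other <- fit_cox(co2, analysis_spec("tvpa", adjustment = "age_accel",
                                        interaction = TRUE))
  expect_error(lrt_interaction(f_other, f_small),
               class = "frailpa_lrt_error")
})

test_that("a strong simulated interaction is detected", {
  lh <- stats::setNames(rep(0, 9), joint_group_levels())
  lh[c("pre_frail_T1", "frail_T1")] <- c(0.3, 0.4)
  lh[c("robust_T2", "robust_T3")] <- c(-0.1, -0.2)
  lh["frail_T3"] <- 1.2   # departure from additivity on the log scale
  hits <- 0
  for (s in 1:10) {
    co <- sim_group_cohort(15000, log_hr = lh, rate_at_50 = 0.03,
                           seed = 820 + s)
    full <- fit_cox(co, analysis_spec("tvpa", adjustment = "age_accel",
                                      interaction = TRUE))
    red <- fit_cox(co, analysis_spec("tvpa", adjustment = "age_accel"))
    hits <- hits + (lrt_interaction(full, red)$lrt_p < 0.05)
  }
  expect_gte(hits, 9)
})

test_that("RERI arithmetic identities hold exactly", {
  mk <- function(b1, b2, b3) {
    hazard_fit(c(e = b1, f = b2, x = b3), diag(0, 3))
  }
  r1 <- reri(mk(log(2), log(1.5), log(4 / 3)), c("e", "f", "x"))
  expect_equal(r1$reri, 1.5)
  expect_equal(c(r1$hr10, r1$hr01, r1$hr11), c(2, 1.5, 4))

  r2 <- reri(mk(0, 0, 0), c("e", "f", "x"))
  expect_equal(r2$reri, 0)

  r3 <- reri(mk(log(2), log(1.5), 0), c("e", "f", "x"))
  expect_equal(r3$reri, 0.5)

  # zero covariance: the bootstrap interval collapses onto the point
  expect_equal(r1$ci_lo, 1.5)
  expect_equal(r1$ci_hi, 1.5)
})

test_that("RERI bootstrap intervals are seeded and sane", {
  v <- matrix(c(0.02, 0.005, 0.001,
                0.005, 0.03, 0.002,
                0.001, 0.002, 0.04), 3, 3)
  fit <- hazard_fit(c(e = log(2), f = log(1.5), x = log(1.2)), v)
  a <- reri(fit, c("e", "f", "x"), n_boot = 2000, seed = 7)
  b <- reri(fit, c("e", "f", "x"), n_boot = 2000, seed = 7)
  expect_identical(a, b)
  expect_true(a$ci_lo <= a$reri && a$reri <= a$ci_hi)
  d <- reri(fit, c("e", "f", "x"), ci_method = "delta")
  expect_equal(d$reri, a$reri)
  # delta and percentile intervals agree to first order
  expect_equal(d$ci_hi - d$ci_lo, a$ci_hi - a$ci_lo, tolerance = 0.25)
  expect_error(reri(fit, c("e", "f", "missing")),
               class = "frailpa_reri_error")
})

test_that("reri_joint reproduces hand-computed contrasts from a joint fit", {
  lv <- joint_group_levels()[-1]
  b <- stats::setNames(seq(0.1, 0.8, length.out = 8),
                       paste0("joint_group", lv))
  fit <- hazard_fit(b, diag(0, 8))
  out <- reri_joint(fit, exposure = "tvpa")
  hr <- function(nm) exp(unname(b[paste0("joint_group", nm)]))
  expect_equal(out$hr10, 1 / hr("robust_T3"))
  expect_equal(out$hr01, hr("frail_T3") / hr("robust_T3"))
  expect_equal(out$hr11, hr("frail_T1") / hr("robust_T3"))
  expect_equal(out$reri, out$hr11 - out$hr10 - out$hr01 + 1)

  out_st <- reri_joint(fit, exposure = "st")
  expect_equal(out_st$hr10, hr("robust_T3"))
  expect_equal(out_st$hr01, hr("frail_T1"))
  expect_equal(out_st$hr11, hr("frail_T3"))
})
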