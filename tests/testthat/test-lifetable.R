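test_that("unit hazard ratios reproduce the population table for every group", {
  pop <- default_pop()
  gs <- group_spec(c("a", "b", "c"), c(0.2, 0.5, 0.3), c(1, 1, 1))
  lt <- build_life_tables(pop, gs, sex = "women")
  d <- tibble::as_tibble(lt)
  mp <- pop$rate[pop$sex == "women"][order(pop$age[pop$sex == "women"])]
  for (g in c("a", "b", "c")) {
    expect_equal(d$m[d$group == g], mp)
  }
  le <- le_at_50(lt)
  expect_equal(diff(range(le$le_at_50)), 0)
})

test_that("the reference rate is the prevalence-weighted normalisation", {
  pop <- default_pop()
  gs <- group_spec(c("ref", "hi"), c(0.5, 0.5), c(1, 2))
  lt <- build_life_tables(pop, gs, sex = "men")
  d <- tibble::as_tibble(lt)
  mp <- pop$rate[pop$sex == "men"][order(pop$age[pop$sex == "men"])]
  expect_equal(d$m[d$group == "ref"], mp / 1.5)
  expect_equal(d$m[d$group == "hi"], 2 * mp / 1.5)
  # exact prevalence consistency at machine precision
  expect_equal(0.5 * d$m[d$group == "ref"] + 0.5 * d$m[d$group == "hi"],
               mp, tolerance = 1e-15)
})

test_that("constant-hazard life expectancy matches the geometric closed form", {
  for (m0 in c(0.005, 0.02, 0.1)) {
    pop1 <- tibble::tibble(age = 50:100, rate = m0)
    lt <- build_life_tables(pop1, group_spec("g", 1, 1))
    oracle <- sum(exp(-m0 * (0:49)) * (1 - (1 - exp(-m0)) / 2)) +
      0.5 * exp(-50 * m0)
    expect_equal(le_at_50(lt)$le_at_50, oracle, tolerance = 1e-10)
  }
})

test_that("life expectancy approaches the capped horizon and zero limits", {
  lo <- build_life_tables(tibble::tibble(age = 50:100, rate = 1e-12),
                          group_spec("g", 1, 1))
  expect_equal(le_at_50(lo)$le_at_50, 50.5, tolerance = 1e-6)
  hi <- build_life_tables(tibble::tibble(age = 50:100, rate = 50),
                          group_spec("g", 1, 1))
  expect_lte(le_at_50(hi)$le_at_50, 0.51)
})

test_that("discrete life expectancy tracks the continuous-time integral", {
  for (m0 in c(0.01, 0.03)) {
    pop1 <- tibble::tibble(age = 50:100, rate = m0)
    lt <- build_life_tables(pop1, group_spec("g", 1, 1))
    analytic <- (1 - exp(-50 * m0)) / m0
    expect_equal(le_at_50(lt)$le_at_50, analytic, tolerance = 0.05)
  }
})

test_that("life expectancy decreases strictly in the hazard ratio", {
  pop <- default_pop()
  gs <- group_spec(paste0("g", 1:5), rep(0.2, 5), c(1, 1.3, 1.8, 2.5, 3.5))
  le <- le_at_50(build_life_tables(pop, gs, sex = "men"))$le_at_50
  expect_true(all(diff(le) < 0))
  d <- tibble::as_tibble(build_life_tables(pop, gs, sex = "men"))
  expect_true(all(d$q >= 0 & d$q <= 1))
  expect_true(all(tapply(d$l, d$group, function(l) all(diff(l) <= 0))))
})

test_that("life-expectancy differences behave and validate", {
  pop <- default_pop()
  gs <- group_spec(c("ref", "mid", "hi"), c(0.4, 0.4, 0.2), c(1, 1.5, 2.5))
  lt <- build_life_tables(pop, gs, sex = "women")
  d <- le_difference(lt, "ref")
  expect_equal(d$delta_years[d$group == "ref"], 0)
  expect_true(d$delta_years[d$group == "hi"] >
                d$delta_years[d$group == "mid"])
  expect_error(le_difference(lt, "nope"), class = "frailpa_le_error")

  # uniformly doubled HRs leave the adjusted rates (hence all deltas)
  # unchanged after the prevalence-weighted renormalisation: verify the
  # fitted rates against direct recomputation with the doubled ratios
  hr2 <- c(1, 1.5, 2.5) * 2
  prev <- c(0.4, 0.4, 0.2)
  mp <- pop$rate[pop$sex == "women"][order(pop$age[pop$sex == "women"])]
  m_direct <- outer(mp / sum(prev * hr2), hr2)
  m_fitted <- matrix(tibble::as_tibble(lt)$m, ncol = 3)
  expect_equal(m_fitted, m_direct, tolerance = 1e-14)
})

test_that("group specifications are validated", {
  expect_error(group_spec(c("a", "b"), c(0.6, 0.6), c(1, 2)),
               class = "frailpa_le_error")
  expect_error(group_spec(c("a", "b"), c(0.5, 0.5), c(1, -2)),
               class = "frailpa_le_error")
  expect_error(group_spec(c("a", "b"), c(0.5, 0.5), c(1.2, 2)),
               class = "frailpa_le_error")
})

test_that("the bootstrap is seeded, degenerate-safe and validated", {
  pop <- default_pop()
  gs <- group_spec(c("ref", "g2", "g3"), c(0.5, 0.3, 0.2), c(1, 1.6, 2.2),
                   coef = c(NA, "b2", "b3"))
  v <- matrix(c(0.02, 0.01, 0.01, 0.03), 2, 2,
              dimnames = list(c("b2", "b3"), c("b2", "b3")))
  fit <- hazard_fit(c(b2 = log(1.6), b3 = log(2.2)), v)

  a <- bootstrap_le_ci(fit, pop, gs, reference = "ref", n_runs = 400,
                       seed = 5, sex = "men")
  b <- bootstrap_le_ci(fit, pop, gs, reference = "ref", n_runs = 400,
                       seed = 5, sex = "men")
  expect_identical(a, b)
  expect_true(all(a$ci_lo <= a$delta_years & a$delta_years <= a$ci_hi))

  fit0 <- hazard_fit(c(b2 = log(1.6), b3 = log(2.2)), matrix(0, 2, 2))
  z <- bootstrap_le_ci(fit0, pop, gs, reference = "ref", n_runs = 200,
                       seed = 5, sex = "men")
  expect_equal(z$ci_lo, z$delta_years)
  expect_equal(z$ci_hi, z$delta_years)

  expect_error(bootstrap_le_ci(fit, pop, gs, reference = "ref",
                               n_runs = 50, seed = 5, sex = "men"),
               class = "frailpa_le_error")

  vneg <- matrix(c(0.02, 0.03, 0.03, 0.02), 2, 2,
                 dimnames = list(c("b2", "b3"), c("b2", "b3")))
  fitneg <- hazard_fit(c(b2 = 0.1, b3 = 0.1), vneg)
  expect_warning(bootstrap_le_ci(fitneg, pop, gs, reference = "ref",
                                 n_runs = 150, seed = 5, sex = "men"),
                 "PSD")
})
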