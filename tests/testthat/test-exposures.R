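test_that("wear validity needs three valid days and weekend data", {
  two_days <- dplyr::bind_rows(make_day(1, 1, "Sat"), make_day(1, 2, "Sun"))
  v <- assess_wear_validity(two_days)
  expect_false(v$valid)
  expect_equal(v$n_valid_days, 2)

  five_weekdays <- dplyr::bind_rows(lapply(1:5, function(i) {
    make_day(2, i, c("Mon", "Tue", "Wed", "Thu", "Fri")[i])
  }))
  v2 <- assess_wear_validity(five_weekdays)
  expect_equal(v2$n_valid_days, 5)
  expect_false(v2$weekend_covered)
  expect_false(v2$valid)

  week <- make_week(3)
  v3 <- assess_wear_validity(week)
  expect_true(v3$valid)

  # a day with under 75% coverage does not count
  thin <- dplyr::bind_rows(make_week(4)[1:(5 * 2880), ],
                           make_day(4, 6, "Sat", coverage = 0.5))
  v4 <- assess_wear_validity(thin)
  expect_equal(v4$n_valid_days, 5)

  empty <- assess_wear_validity(make_day(1, 1, "Mon")[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("behaviour hours and awake ENMO aggregate as defined", {
  # sixty 30-s mvpa epochs in one day inside the window -> 0.5 h/day
  week <- make_week(1, n_mvpa = 60, enmo = 40)
  agg <- aggregate_epochs(week)
  expect_equal(agg$mvpa_h_day, 0.5)
  expect_equal(agg$lpa_h_day, 600 / 120)
  expect_equal(agg$st_h_day, 960 / 120)
  # constant ENMO of 40 mg across awake epochs -> tvpa 40
  expect_equal(agg$tvpa_mg, 40)
})

test_that("the awake window boundary is half-open at 30-s resolution", {
  week <- make_week(1, enmo = 40)
  # mark the epochs at 05:59:30 and 06:00:00 with distinctive ENMO
  week$enmo_mg[week$epoch_start == 21570] <- 1e6
  agg <- aggregate_epochs(week)
  expect_equal(agg$tvpa_mg, 40)       # 05:59:30 excluded
  week$enmo_mg[week$epoch_start == 21600] <- 40 + 1920
  agg2 <- aggregate_epochs(week)
  # 06:00:00 included: one of 1920 awake epochs each day gains +1920
  expect_equal(agg2$tvpa_mg, 41)
})

test_that("narrowing the awake window never increases behaviour totals", {
  cfg <- cohort_config(n_participants = 40, seed = 23,
                       n_epoch_participants = 40)
  sim <- generate_cohort(cfg)
  wide <- aggregate_epochs(sim$epochs, window = "06:00-22:00")
  for (w in c("07:00-21:00", "08:00-20:00")) {
    narrow <- aggregate_epochs(sim$epochs, window = w)
    tot_w <- wide$mvpa_h_day + wide$lpa_h_day + wide$st_h_day
    tot_n <- narrow$mvpa_h_day + narrow$lpa_h_day + narrow$st_h_day
    expect_true(all(tot_n <= tot_w + 1e-12))
  }
})

test_that("tertile assignment cuts at the sample tertiles with T1 reference", {
  t <- assign_tertiles(1:9)
  expect_equal(as.character(t$labels),
               rep(c("T1", "T2", "T3"), each = 3))
  expect_equal(t$scheme$reference_tertile, "T1")

  v <- rnorm(100)
  expect_equal(as.character(assign_tertiles(v)$labels[which.min(v)]), "T1")

  set.seed(9)
  u <- runif(30000)
  sizes <- table(assign_tertiles(u)$labels)
  expect_true(all(abs(sizes - 10000) <= 1))

  expect_error(assign_tertiles(c(1, 1, 1, 1)),
               class = "frailpa_tertile_error")
  expect_error(assign_tertiles(c(1, 2)), class = "frailpa_tertile_error")
})

test_that("tertile labels are invariant to monotone transformation", {
  set.seed(10)
  v <- rlnorm(500)
  expect_identical(assign_tertiles(v)$labels,
                   assign_tertiles(log(v))$labels)
  expect_identical(assign_tertiles(v)$labels,
                   assign_tertiles(rank(v))$labels)
})

test_that("awake-window strings are validated", {
  w <- parse_awake_window("06:00-22:00")
  expect_equal(w$hours, 16)
  expect_error(parse_awake_window("22:00-06:00"),
               class = "frailpa_window_error")
  expect_error(parse_awake_window("6am-10pm"),
               class = "frailpa_window_error")
})
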