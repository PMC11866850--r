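test_that("deficit coding maps levels to scores and propagates missingness", {
  cb <- default_deficit_codebook()
  expect_equal(nrow(cb), 49)
  diabetes <- cb[cb$item == "diabetes", ]
  expect_equal(code_deficit("yes", diabetes), 1)
  expect_equal(code_deficit("no", diabetes), 0)
  expect_true(is.na(code_deficit(NA, diabetes)))
  expect_error(code_deficit("maybe", diabetes),
               class = "frailpa_coding_error")

  # equal spacing: the middle level of a 3-level ordinal scores 0.5
  mem <- cb[cb$item == "memory_self_rated", ]
  expect_equal(code_deficit("average", mem), 0.5)
  expect_equal(code_deficit("good", mem), 0)
  expect_equal(code_deficit("poor", mem), 1)
})

test_that("the frailty index follows the deficit-accumulation formula", {
  s <- c(rep(1, 7), rep(0, 42))
  out <- compute_fi(s)
  expect_equal(out$fi, 7 / 49)
  expect_equal(as.character(out$fi_category), "pre_frail")
  expect_equal(compute_fi(rep(0, 49))$fi, 0)
  expect_equal(as.character(compute_fi(rep(0, 49))$fi_category), "robust")
  expect_equal(compute_fi(rep(1, 49))$fi, 1)
  expect_equal(as.character(compute_fi(rep(1, 49))$fi_category), "frail")
  expect_error(compute_fi(numeric(0)), class = "frailpa_fi_error")
})

test_that("missing items flag the record incomplete unless a quorum is set", {
  s <- c(NA, rep(0, 48))
  expect_true(is.na(compute_fi(s)$fi))
  out <- compute_fi(s, min_fraction_scored = 0.9)
  expect_equal(out$fi, 0)
  expect_equal(out$n_items_scored, 48L)
  expect_true(is.na(compute_fi(rep(NA_real_, 49),
                               min_fraction_scored = 0.9)$fi))
})

test_that("fi bounds, monotonicity and permutation invariance hold", {
  set.seed(42)
  for (i in 1:25) {
    s <- runif(49)
    fi <- compute_fi(s)$fi
    expect_gte(fi, 0)
    expect_lte(fi, 1)
    j <- sample.int(49, 1)
    s2 <- s
    s2[j] <- min(1, s[j] + runif(1, 0, 1 - s[j]))
    expect_gte(compute_fi(s2)$fi, fi)
    expect_equal(compute_fi(sample(s))$fi, fi)
  }
})

test_that("category boundaries assign 0.12 to robust and 0.24 to frail", {
  expect_equal(as.character(classify_fi(0.12)), "robust")
  expect_equal(as.character(classify_fi(0.24)), "frail")
  expect_equal(as.character(classify_fi(0.18)), "pre_frail")
  expect_equal(as.character(classify_fi(c(0, 1))), c("robust", "frail"))
  expect_error(classify_fi(1.2), class = "frailpa_fi_error")
})

test_that("codebooks survive a JSON and CSV round trip", {
  cb <- default_deficit_codebook()
  fj <- withr::local_tempfile(fileext = ".json")
  fc <- withr::local_tempfile(fileext = ".csv")
  write_deficit_codebook(cb, fj)
  write_deficit_codebook(cb, fc)
  rj <- read_deficit_codebook(fj)
  rc <- read_deficit_codebook(fc)
  for (r in list(rj, rc)) {
    r <- r[match(cb$item, r$item), ]
    expect_equal(r$kind, cb$kind)
    expect_equal(r$levels, cb$levels)
    expect_equal(r$scores, cb$scores)
  }
})

test_that("add_frailty_index matches per-row scoring on generated data", {
  cfg <- small_config(n = 200, seed = 3, deficit_missing_rate = 0.1)
  co <- generate_cohort(cfg, epochs = FALSE)$cohort |>
    dplyr::select(-fi, -fi_category, -fi_complete)
  out <- add_frailty_index(co)
  expect_true(all(is.na(out$fi[!out$fi_complete])))
  i <- which(out$fi_complete)[1]
  scores <- code_deficits(out[i, ])
  expect_equal(out$fi[i], sum(scores) / 49)
})
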