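#' Synthetic ONS-style population mortality rates
#'
#' A sex- and age-specific annual all-cause mortality schedule for ages
#' 50-100 following a Gompertz law with realistic national-level parameters
#' (men start higher and both sexes double roughly every 7.5 years). This is
#' a synthetic stand-in for a national statistics life table, shipped so the
#' life-expectancy stage runs without any download; the same table is
#' available as a CSV via `system.file("extdata",
#' "synthetic_population_rates.csv", package = "frailpa")`.
#'
#' @param rate_at_50 Named vector: annual mortality rate at age 50 per sex.
#' @param doubling_years Named vector: rate-doubling time per sex.
#' @return Tibble with columns `sex` (`"women"`/`"men"`), `age` (50..100)
#'   and `rate` (events/person-year).
#' @export
synthetic_population_rates <- function(rate_at_50 = c(women = 0.0020,
                                                      men = 0.0032),
                                       doubling_years = c(women = 7.6,
                                                          men = 7.4)) {
  ages <- 50:100
  bind_rows(lapply(c("women", "men"), function(s) {
    tibble(sex = s, age = ages,
           rate = rate_at_50[[s]] *
             exp(log(2) / doubling_years[[s]] * (ages - 50)))
  }))
}

#' Read a population mortality-rate table
#'
#' Expects CSV columns `sex`, `age`, `rate`; validates that ages 50..100 are
#' complete for every sex and that all rates are positive.
#'
#' @param path CSV path.
#' @return Validated tibble.
#' @export
read_population_rates <- function(path) {
  pop <- readr::read_csv(path, show_col_types = FALSE)
  validate_population_rates(pop)
  pop
}

validate_population_rates <- function(pop) {
  stopifnot(all(c("sex", "age", "rate") %in% names(pop)))
  if (any(pop$rate <= 0)) {
    abort("Population rates must be positive.", class = "frailpa_le_error")
  }
  for (s in unique(pop$sex)) {
    ages <- sort(pop$age[pop$sex == s])
    if (!identical(as.integer(ages), 50:100)) {
      abort(sprintf("Ages 50..100 must be complete for sex '%s'.", s),
            class = "frailpa_le_error")
    }
  }
  invisible(pop)
}

#' Specify the exposure groups for life-table adjustment
#'
#' @param group Character labels (e.g. the nine joint FI-by-tertile states).
#' @param prevalence Group prevalences summing to 1.
#' @param hr Hazard ratios versus the reference group (reference = 1).
#' @param coef Optional coefficient names linking each non-reference group
#'   to a term of a `frailpa_cox` fit (used by [bootstrap_le_ci()]); `NA`
#'   for the reference.
#' @return A validated tibble of class `frailpa_groups`.
#' @export
group_spec <- function(group, prevalence, hr, coef = NULL) {
  spec <- tibble(group = as.character(group), prevalence = prevalence,
                 hr = hr)
  if (!is.null(coef)) spec$coef <- coef
  if (abs(sum(spec$prevalence) - 1) > 1e-9) {
    abort("Group prevalences must sum to 1.", class = "frailpa_le_error")
  }
  if (any(spec$hr <= 0)) {
    abort("Hazard ratios must be positive.", class = "frailpa_le_error")
  }
  if (!any(spec$hr == 1)) {
    abort("A reference group with hr = 1 is required.",
          class = "frailpa_le_error")
  }
  structure(spec, class = c("frailpa_groups", class(spec)))
}

# Core engine: population rates + per-group HRs -> per-group life columns.
# Returns list(le = named vector, tables = list of per-group tibbles or NULL)
life_engine <- function(m_pop, hr, prevalence, keep_tables = TRUE) {
  w <- sum(prevalence * hr)
  m_ref <- m_pop / w
  m <- outer(m_ref, hr)                    # ages x groups
  q <- -expm1(-m)
  q[nrow(q), ] <- 1                        # closed cohort at age 100
  n_age <- nrow(q)
  l <- rbind(1, apply(1 - q[-n_age, , drop = FALSE], 2, cumprod))
  bigL <- l * (1 - q / 2)
  list(le = colSums(bigL), m = m, q = q, l = l, bigL = bigL)
}

#' Build hazard-ratio- and prevalence-adjusted life tables
#'
#' Back-calculates the reference-group mortality from the population rate by
#' prevalence-weighted HR normalisation,
#' `m_ref(a) = m_pop(a) / sum_g p_g * hr_g`, applies each group's hazard
#' ratio (`m_g = m_ref * hr_g`), converts rates to death probabilities
#' `q = 1 - exp(-m)`, and accumulates survivorship from age 50 with
#' person-years `L(a) = l(a) * (1 - q(a)/2)`. The cohort is closed at age
#' 100 (`q(100) = 1`), so residual life expectancy at 50 is
#' `sum_{a=50}^{100} L(a)`. By construction the prevalence-weighted group
#' rates reproduce the population rate exactly at every age.
#'
#' @param pop Population rates tibble (`sex`, `age`, `rate`) or just
#'   (`age`, `rate`) when `sex` is `NULL`.
#' @param groups A [group_spec()].
#' @param sex Optional sex to select from `pop`.
#' @return Tibble of class `frailpa_lifetable`: `group`, `age`, `m`, `q`,
#'   `l`, `L`, with the per-group life expectancies in attribute `"le"`.
#' @export
build_life_tables <- function(pop, groups, sex = NULL) {
  if (!is.null(sex)) pop <- pop[pop$sex == sex, ]
  pop <- pop[order(pop$age), ]
  if (!identical(as.integer(pop$age), 50:100)) {
    abort("Population table must cover ages 50..100 exactly once.",
          class = "frailpa_le_error")
  }
  if (any(pop$rate <= 0)) {
    abort("Population rates must be positive.", class = "frailpa_le_error")
  }
  if (!inherits(groups, "frailpa_groups")) {
    abort("`groups` must be a group_spec().", class = "frailpa_le_error")
  }
  eng <- life_engine(pop$rate, groups$hr, groups$prevalence)
  k <- nrow(groups)
  out <- tibble(
    group = rep(groups$group, each = 51),
    age = rep(50:100, times = k),
    m = as.vector(eng$m),
    q = as.vector(eng$q),
    l = as.vector(eng$l),
    L = as.vector(eng$bigL)
  )
  structure(out, class = c("frailpa_lifetable", class(out)),
            le = tibble(group = groups$group,
                        le_at_50 = unname(eng$le)),
            groups = groups, m_pop = pop$rate, sex = sex)
}

#' Life expectancy at age 50 per group
#'
#' @param tables A `frailpa_lifetable` from [build_life_tables()].
#' @return Tibble `group`, `le_at_50` (years).
#' @export
le_at_50 <- function(tables) attr(tables, "le")

#' Life-expectancy differences versus a reference group
#'
#' `delta_years = LE_reference - LE_group`: positive values are years of
#' life lost relative to the reference.
#'
#' @param tables A `frailpa_lifetable`.
#' @param reference Reference group label, or a named character vector
#'   mapping each group to its own reference (e.g. the top tertile of the
#'   same frailty category).
#' @return Tibble `group`, `reference`, `le_at_50`, `delta_years`.
#' @export
le_difference <- function(tables, reference) {
  le <- le_at_50(tables)
  refs <- resolve_reference(le$group, reference)
  tibble(group = le$group, reference = refs,
         le_at_50 = le$le_at_50,
         delta_years = le$le_at_50[match(refs, le$group)] - le$le_at_50)
}

resolve_reference <- function(group, reference) {
  if (length(reference) == 1 && is.null(names(reference))) {
    if (!reference %in% group) {
      abort(sprintf("Unknown reference group '%s'.", reference),
            class = "frailpa_le_error")
    }
    return(rep(reference, length(group)))
  }
  refs <- reference[group]
  if (any(is.na(refs)) || !all(refs %in% group)) {
    abort("Reference mapping must name every group and point at known groups.",
          class = "frailpa_le_error")
  }
  unname(refs)
}

#' Parametric-bootstrap confidence intervals for life-expectancy differences
#'
#' Monte-Carlo propagation of hazard-ratio uncertainty into the life table:
#' each run draws the group log hazard ratios from a multivariate normal
#' around the fitted coefficients, rebuilds all group life tables (with
#' prevalences held at their observed values) and records the
#' life-expectancy differences; the interval is the 2.5/97.5 percentile of
#' the runs.
#'
#' @param fit A `frailpa_cox` supplying coefficients and covariance for the
#'   group terms named in `groups$coef`.
#' @param pop Population rates tibble.
#' @param groups A [group_spec()] with a `coef` column.
#' @param reference Reference group label or named mapping
#'   (see [le_difference()]).
#' @param n_runs Number of bootstrap runs (>= 100; default 10,000).
#' @param seed Integer seed.
#' @param sex Optional sex selector for `pop`.
#' @return Tibble of class `frailpa_le`: `group`, `reference`,
#'   `delta_years`, `ci_lo`, `ci_hi`, `n_bootstrap`.
#' @export
bootstrap_le_ci <- function(fit, pop, groups, reference, n_runs = 10000,
                            seed = 1L, sex = NULL) {
  if (n_runs < 100) {
    abort("`n_runs` must be at least 100.", class = "frailpa_le_error")
  }
  if (!"coef" %in% names(groups)) {
    abort("`groups` must carry a `coef` column naming the fit terms.",
          class = "frailpa_le_error")
  }
  if (!is.null(sex)) pop <- pop[pop$sex == sex, ]
  pop <- pop[order(pop$age), ]
  cn <- groups$coef[!is.na(groups$coef)]
  if (!all(cn %in% names(coef(fit)))) {
    abort(paste0("Fit lacks group term(s): ",
                 paste(setdiff(cn, names(coef(fit))), collapse = ", ")),
          class = "frailpa_le_error")
  }
  b <- coef(fit)[cn]
  v <- vcov(fit)[cn, cn, drop = FALSE]
  ev <- eigen((v + t(v)) / 2, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    warn("Coefficient covariance is not PSD; projecting onto the PSD cone.")
  }
  vals <- pmax(ev$values, 0)
  v <- ev$vectors %*% (vals * t(ev$vectors))

  set.seed(seed)
  draws <- MASS::mvrnorm(n_runs, mu = b, Sigma = v)
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = n_runs)
  colnames(draws) <- cn

  idx <- match(groups$coef, cn)            # NA for the reference group
  refs <- resolve_reference(groups$group, reference)
  ref_idx <- match(refs, groups$group)
  m_pop <- pop$rate
  prev <- groups$prevalence

  point_le <- life_engine(m_pop, groups$hr, prev)$le
  point_delta <- point_le[ref_idx] - point_le

  deltas <- matrix(NA_real_, n_runs, nrow(groups))
  for (r in seq_len(n_runs)) {
    hr_r <- ifelse(is.na(idx), 1, exp(draws[r, ][idx]))
    le_r <- life_engine(m_pop, hr_r, prev, keep_tables = FALSE)$le
    deltas[r, ] <- le_r[ref_idx] - le_r
  }
  ci <- apply(deltas, 2, quantile, probs = c(0.025, 0.975))
  out <- tibble(group = groups$group, reference = refs,
                delta_years = unname(point_delta),
                ci_lo = pmin(ci[1, ], point_delta),
                ci_hi = pmax(ci[2, ], point_delta),
                n_bootstrap = as.integer(n_runs))
  structure(out, class = c("frailpa_le", class(out)))
}
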