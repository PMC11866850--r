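#' Default adjustment covariate set
#'
#' The standard confounder list: age at accelerometer measurement, sex,
#' assessment centre, BMI category, ethnicity, education, employment,
#' household income, Townsend deprivation index, smoking, alcohol frequency,
#' sleep duration, healthy diet score, three family histories, seasonality
#' and total wear days.
#'
#' @return Character vector of cohort column names.
#' @export
default_adjustment <- function() {
  c("age_accel", "sex", "assessment_centre", "bmi_cat", "ethnicity",
    "education", "employment", "income", "townsend", "smoking", "alcohol",
    "sleep_duration", "diet_score", "famhx_diabetes", "famhx_cvd",
    "famhx_cancer", "season", "wear_days")
}

exposure_value_col <- function(exposure) {
  c(tvpa = "tvpa_mg", mvpa = "mvpa_h_day", lpa = "lpa_h_day",
    st = "st_h_day")[[exposure]]
}

#' Specify a proportional-hazards analysis
#'
#' Declares which exposure is modelled, in what form, how frailty enters,
#' and the adjustment set. Mutual adjustment follows the study rule: MVPA
#' and LPA models additionally adjust for sedentary time, the ST model for
#' MVPA, and the TVPA model for neither.
#'
#' @param exposure One of `"tvpa"`, `"mvpa"`, `"lpa"`, `"st"`.
#' @param exposure_form `"tertile"` (factor with T1 reference),
#'   `"continuous"` (linear term) or `"spline"` (restricted cubic spline;
#'   used by [rcs_dose_response()]).
#' @param fi_form `"category"` (frailty as a 3-level factor), `"joint"`
#'   (nine mutually exclusive FI-by-tertile groups) or `"none"`.
#' @param adjustment Character vector of adjustment covariates.
#' @param mutual_adjustment Apply the mutual-adjustment rule (default TRUE).
#' @param interaction Add the exposure-by-frailty cross-product (only with
#'   `fi_form = "category"`).
#' @param extra_adjustment Additional covariate columns (e.g. mutual MVPA/LPA
#'   adjustment in sensitivity analyses).
#' @return A list of class `frailpa_spec`.
#' @export
analysis_spec <- function(exposure = c("tvpa", "mvpa", "lpa", "st"),
                          exposure_form = c("tertile", "continuous", "spline"),
                          fi_form = c("category", "joint", "none"),
                          adjustment = default_adjustment(),
                          mutual_adjustment = TRUE,
                          interaction = FALSE,
                          extra_adjustment = character()) {
  exposure <- match.arg(exposure)
  exposure_form <- match.arg(exposure_form)
  fi_form <- match.arg(fi_form)
  mutual <- character()
  if (mutual_adjustment) {
    mutual <- switch(exposure,
                     mvpa = "st_h_day", lpa = "st_h_day",
                     st = "mvpa_h_day", tvpa = character())
  }
  structure(list(exposure = exposure, exposure_form = exposure_form,
                 fi_form = fi_form, adjustment = adjustment,
                 mutual = mutual, interaction = interaction,
                 extra_adjustment = extra_adjustment),
            class = "frailpa_spec")
}

#' Construct a hazard-model fit object directly
#'
#' Wraps coefficients, their covariance, a log-likelihood and the event
#' count into the fit container used throughout the package; useful for
#' analyses that start from published coefficients rather than individual
#' data (e.g. feeding [bootstrap_le_ci()] or [reri()]).
#'
#' @param coefficients Named numeric vector of log hazard ratios.
#' @param vcov Covariance matrix of the coefficients (symmetric PSD).
#' @param loglik Maximised log partial likelihood (optional).
#' @param n_events Number of events (optional).
#' @param model Underlying `coxph` fit, if any.
#' @param spec The `frailpa_spec`, if any.
#' @return An object of class `frailpa_cox`.
#' @export
hazard_fit <- function(coefficients, vcov, loglik = NA_real_,
                       n_events = NA_integer_, model = NULL, spec = NULL) {
  vcov <- as.matrix(vcov)
  if (nrow(vcov) != length(coefficients) ||
      any(abs(vcov - t(vcov)) > 1e-8)) {
    abort("`vcov` must be a symmetric matrix matching the coefficients.",
          class = "frailpa_fit_error")
  }
  dimnames(vcov) <- list(names(coefficients), names(coefficients))
  structure(list(coefficients = coefficients, vcov = vcov, loglik = loglik,
                 n_events = as.integer(n_events), ties = "efron",
                 model = model, spec = spec),
            class = "frailpa_cox")
}

#' @export
coef.frailpa_cox <- function(object, ...) object$coefficients

#' @export
vcov.frailpa_cox <- function(object, ...) object$vcov

#' @export
logLik.frailpa_cox <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}

#' @export
print.frailpa_cox <- function(x, ...) {
  cat("<frailpa_cox> Cox proportional-hazards fit (Efron ties)\n")
  cat("  terms:", length(x$coefficients), " events:", x$n_events,
      " logLik:", format(x$loglik), "\n")
  invisible(x)
}

check_no_missing <- function(data, cols) {
  miss <- cols[map_lgl(cols, function(cl) anyNA(data[[cl]]))]
  if (length(miss)) {
    abort(paste0("Missing values in modelled column(s): ",
                 paste(miss, collapse = ", "),
                 ". Impute or exclude upstream."),
          class = "frailpa_fit_error")
  }
}

check_events_per_level <- function(data, cols) {
  for (cl in cols) {
    v <- data[[cl]]
    if (is.factor(v) || is.character(v)) {
      v <- factor(v)
      used <- levels(v)[levels(v) %in% unique(as.character(v))]
      ev <- tapply(data$event, factor(as.character(v), levels = used), sum)
      zero <- names(ev)[is.na(ev) | ev == 0]
      if (length(zero)) {
        abort(sprintf("No events in level(s) %s of '%s'; the model is not identifiable.",
                      paste(zero, collapse = ", "), cl),
              class = "frailpa_fit_error")
      }
    }
  }
}

rhs_terms <- function(cohort, spec) {
  adj <- c(spec$adjustment, spec$mutual, spec$extra_adjustment)
  adj <- setdiff(adj, switch(spec$exposure,
                             mvpa = "mvpa_h_day", lpa = "lpa_h_day",
                             st = "st_h_day", tvpa = "tvpa_mg"))
  if (spec$fi_form == "joint") {
    main <- "joint_group"
  } else {
    exp_term <- switch(spec$exposure_form,
                       tertile = paste0(spec$exposure, "_tertile"),
                       continuous = exposure_value_col(spec$exposure),
                       spline = abort("Use rcs_dose_response() for splines.",
                                      class = "frailpa_fit_error"))
    main <- exp_term
    if (spec$fi_form == "category") {
      main <- c(main, "fi_category")
      if (isTRUE(spec$interaction)) {
        main <- c(main, paste0(exp_term, ":fi_category"))
      }
    }
  }
  list(main = main, adjustment = adj)
}

#' Fit an adjusted Cox proportional-hazards model
#'
#' Maximises the partial likelihood with the Efron approximation for tied
#' event times on the month timescale. Missing values in any modelled
#' column are an error (imputation happens upstream), as is a categorical
#' level with no events.
#'
#' @param cohort Cohort tibble with `time_months` and logical `event`.
#' @param spec An [analysis_spec()].
#' @return A `frailpa_cox` object: coefficients (log HRs), covariance,
#'   log partial likelihood, event count, the underlying `coxph` fit and
#'   the spec.
#' @export
fit_cox <- function(cohort, spec) {
  stopifnot(inherits(spec, "frailpa_spec"))
  tm <- rhs_terms(cohort, spec)
  plain_cols <- setdiff(unique(c(tm$main, tm$adjustment)),
                        grep(":", tm$main, value = TRUE))
  if (spec$fi_form == "joint" && !"joint_group" %in% names(cohort)) {
    cohort <- add_joint_group(cohort, spec$exposure)
  }
  check_no_missing(cohort, c("time_months", "event", plain_cols))
  check_events_per_level(cohort, plain_cols)
  fml <- stats::reformulate(c(tm$main, tm$adjustment),
                            response = "survival::Surv(time_months, event)")
  fit <- survival::coxph(fml, data = cohort, ties = "efron",
                         model = FALSE, x = FALSE, y = TRUE)
  if (any(is.na(coef(fit)))) {
    abort(paste0("Inestimable term(s): ",
                 paste(names(coef(fit))[is.na(coef(fit))], collapse = ", ")),
          class = "frailpa_fit_error")
  }
  hazard_fit(coef(fit), stats::vcov(fit), loglik = fit$loglik[2],
             n_events = fit$nevent, model = fit, spec = spec)
}

#' Build the nine-level joint FI-by-tertile factor
#'
#' @param cohort Cohort with `fi_category` and `<exposure>_tertile` (the
#'   tertile column is derived on the fly if absent).
#' @param exposure Exposure name.
#' @return The cohort with a `joint_group` factor column (reference level
#'   `robust_T1`).
#' @export
add_joint_group <- function(cohort, exposure) {
  tcol <- paste0(exposure, "_tertile")
  if (!tcol %in% names(cohort)) {
    cohort[[tcol]] <- assign_tertiles(cohort[[exposure_value_col(exposure)]],
                                      exposure)$labels
  }
  cohort$joint_group <- factor(
    paste(as.character(cohort$fi_category), as.character(cohort[[tcol]]),
          sep = "_"),
    levels = joint_group_levels())
  cohort
}

#' Joint-group hazard ratios
#'
#' Stratifies the sample into nine mutually exclusive groups (3 frailty
#' categories x 3 exposure tertiles), fits a single adjusted Cox model with
#' indicator coding against the robust-by-reference-tertile group, and
#' returns the hazard ratios with Wald 95% confidence intervals.
#'
#' @param cohort Cohort tibble.
#' @param spec An [analysis_spec()]; `fi_form` is forced to `"joint"`.
#' @return A tibble of class `frailpa_joint` with 9 rows: `group`,
#'   `fi_category`, `tertile`, `n`, `n_events`, `hr`, `ci_lo`, `ci_hi`,
#'   `is_reference`; the underlying fit is attached as attribute `"fit"`.
#' @export
joint_group_hrs <- function(cohort, spec) {
  spec$fi_form <- "joint"
  cohort <- add_joint_group(cohort, spec$exposure)
  tab <- cohort |>
    group_by(.data$joint_group, .drop = FALSE) |>
    summarise(n = dplyr::n(), n_events = sum(.data$event), .groups = "drop")
  bad <- tab$joint_group[tab$n == 0 | tab$n_events == 0]
  if (length(bad)) {
    abort(paste0("Joint group(s) empty or without events: ",
                 paste(as.character(bad), collapse = ", ")),
          class = "frailpa_fit_error")
  }
  fit <- fit_cox(cohort, spec)
  z <- qnorm(0.975)
  lv <- joint_group_levels()
  cn <- paste0("joint_group", lv[-1])
  b <- coef(fit)[cn]
  se <- sqrt(diag(vcov(fit))[cn])
  out <- tibble(
    group = lv,
    fi_category = sub("_T[123]$", "", lv),
    tertile = sub("^.*_(T[123])$", "\\1", lv),
    hr = unname(c(1, exp(b))),
    ci_lo = unname(c(1, exp(b - z * se))),
    ci_hi = unname(c(1, exp(b + z * se))),
    is_reference = lv == "robust_T1"
  ) |>
    left_join(tab |> rename(group = "joint_group") |>
                mutate(group = as.character(.data$group)),
              by = "group") |>
    select("group", "fi_category", "tertile", "n", "n_events",
           "hr", "ci_lo", "ci_hi", "is_reference")
  structure(out, class = c("frailpa_joint", class(out)), fit = fit)
}

#' Likelihood-ratio test for multiplicative interaction
#'
#' Compares a full model containing the exposure-by-frailty cross-product
#' with the reduced model without it: `stat = 2 * (llik_full - llik_reduced)`
#' (clipped at zero), with degrees of freedom equal to the difference in
#' parameter count and a chi-square upper-tail p-value.
#'
#' @param fit_full,fit_reduced `frailpa_cox` fits on the same data, the
#'   reduced model nested in the full one.
#' @return A tibble: `lrt_stat`, `lrt_df`, `lrt_p`.
#' @export
lrt_interaction <- function(fit_full, fit_reduced) {
  df <- length(coef(fit_full)) - length(coef(fit_reduced))
  if (df < 0) {
    abort("The reduced model has more parameters than the full model.",
          class = "frailpa_lrt_error")
  }
  same <- isTRUE(fit_full$n_events == fit_reduced$n_events)
  if (!same) {
    abort("Models were not fitted on the same event set; they are not nested.",
          class = "frailpa_lrt_error")
  }
  if (df == 0 && abs(fit_full$loglik - fit_reduced$loglik) > 1e-8) {
    abort("Models have equal size but different likelihoods; not nested.",
          class = "frailpa_lrt_error")
  }
  stat <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  tibble(lrt_stat = stat, lrt_df = as.integer(df), lrt_p = p)
}

#' Relative excess risk due to interaction (RERI)
#'
#' Additive-scale interaction between a binary exposure and a binary frailty
#' contrast sharing a common reference:
#' `RERI = HR11 - HR10 - HR01 + 1`, where `HR10` and `HR01` are the two main
#' effects and `HR11 = exp(b10 + b01 + b_joint)` is the doubly exposed group.
#' The confidence interval is a seeded parametric bootstrap over
#' `beta* ~ MVN(beta_hat, Sigma)` (percentile 2.5/97.5); a delta-method
#' interval is available as an option.
#'
#' @param fit A `frailpa_cox` fit.
#' @param terms Character vector of length 3 naming, in order, the exposure
#'   main-effect, frailty main-effect and interaction coefficients in `fit`.
#' @param ci_method `"bootstrap"` (default) or `"delta"`.
#' @param n_boot Number of bootstrap draws.
#' @param seed Seed for the bootstrap.
#' @return A tibble: `hr10`, `hr01`, `hr11`, `reri`, `ci_lo`, `ci_hi`,
#'   `method`.
#' @export
reri <- function(fit, terms, ci_method = c("bootstrap", "delta"),
                 n_boot = 10000, seed = 1L) {
  ci_method <- match.arg(ci_method)
  b <- coef(fit)
  if (!all(terms %in% names(b))) {
    abort(paste0("Fit lacks required term(s): ",
                 paste(setdiff(terms, names(b)), collapse = ", ")),
          class = "frailpa_reri_error")
  }
  v <- vcov(fit)[terms, terms]
  bb <- b[terms]
  reri_of <- function(b3) {
    unname(exp(b3[1] + b3[2] + b3[3]) - exp(b3[1]) - exp(b3[2]) + 1)
  }
  point <- reri_of(bb)
  if (ci_method == "bootstrap") {
    set.seed(seed)
    draws <- MASS::mvrnorm(n_boot, mu = bb, Sigma = v)
    vals <- exp(rowSums(draws)) - exp(draws[, 1]) - exp(draws[, 2]) + 1
    ci <- unname(quantile(vals, c(0.025, 0.975)))
    # degenerate covariance: all draws identical, zero-width interval at point
  } else {
    h11 <- exp(sum(bb))
    g <- c(h11 - exp(bb[1]), h11 - exp(bb[2]), h11)
    se <- sqrt(drop(t(g) %*% v %*% g))
    ci <- point + c(-1, 1) * qnorm(0.975) * se
  }
  tibble(hr10 = exp(bb[[1]]), hr01 = exp(bb[[2]]),
         hr11 = exp(sum(bb)), reri = point,
         ci_lo = min(ci[1], point), ci_hi = max(ci[2], point),
         method = ci_method)
}

#' Proportional-hazards diagnostics from scaled Schoenfeld residuals
#'
#' Per-term association tests of the scaled Schoenfeld residuals against the
#' rank of event time, plus the global test.
#'
#' @param fit A `frailpa_cox` fit carrying its `coxph` model.
#' @return A tibble of class `frailpa_ph`: `term`, `chisq`, `df`, `p`, with
#'   `GLOBAL` as the last row.
#' @export
ph_check <- function(fit) {
  if (is.null(fit$model)) {
    abort("`fit` does not carry a coxph model.", class = "frailpa_ph_error")
  }
  if (is.na(fit$n_events) || fit$n_events < 2) {
    abort("At least two events are required for the diagnostic.",
          class = "frailpa_ph_error")
  }
  zp <- survival::cox.zph(fit$model, transform = "rank", global = TRUE)
  tab <- as.data.frame(zp$table)
  out <- tibble(term = rownames(tab), chisq = tab$chisq,
                df = tab$df, p = tab$p)
  structure(out, class = c("frailpa_ph", class(out)))
}
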