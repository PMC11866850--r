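#' Apply cohort exclusion rules
#'
#' Applies the declared rules in order, mirroring the study's selection flow
#' (wear validity, complete frailty-index data, mortality linkage, minimum
#' age, plus optional sensitivity exclusions), and returns a telescoping log.
#'
#' Available rules: `invalid_wear` (fewer than 3 valid days or no weekend
#' data), `incomplete_fi` (any of the 49 deficit items missing),
#' `missing_mortality`, `age_lt_45`, `landmark_2yr` (deaths within the first
#' two years of follow-up), `shift_worker`.
#'
#' @param cohort Cohort tibble.
#' @param rules Character vector of rule names, applied in order.
#' @return List with `cohort` (filtered tibble) and `log` (tibble `rule`,
#'   `n_before`, `n_removed`, `n_after`).
#' @export
apply_exclusions <- function(cohort,
                             rules = c("invalid_wear", "incomplete_fi",
                                       "missing_mortality", "age_lt_45")) {
  predicates <- list(
    invalid_wear = function(d) d$valid_wear,
    incomplete_fi = function(d) {
      if ("fi_complete" %in% names(d)) {
        d$fi_complete
      } else {
        def <- d[, grep("^def_", names(d)), drop = FALSE]
        complete.cases(def)
      }
    },
    missing_mortality = function(d) !is.na(d$time_months) & !is.na(d$event),
    age_lt_45 = function(d) d$age_accel >= 45,
    landmark_2yr = function(d) !(d$event & d$time_months < 24),
    shift_worker = function(d) !d$shift_worker
  )
  unknown <- setdiff(rules, names(predicates))
  if (length(unknown)) {
    abort(paste0("Unknown exclusion rule(s): ",
                 paste(unknown, collapse = ", ")),
          class = "frailpa_exclusion_error")
  }
  log <- vector("list", length(rules))
  for (i in seq_along(rules)) {
    n_before <- nrow(cohort)
    keep <- predicates[[rules[i]]](cohort)
    keep[is.na(keep)] <- FALSE
    cohort <- cohort[keep, ]
    log[[i]] <- tibble(rule = rules[i], n_before = n_before,
                       n_removed = n_before - nrow(cohort),
                       n_after = nrow(cohort))
  }
  list(cohort = cohort,
       log = if (length(log)) bind_rows(log) else
         tibble(rule = character(), n_before = integer(),
                n_removed = integer(), n_after = integer()))
}

impute_simple_values <- function(x) {
  if (is.numeric(x)) {
    median(x, na.rm = TRUE)
  } else {
    tab <- sort(table(x), decreasing = TRUE)
    names(tab)[1]
  }
}

#' Impute missing covariate values
#'
#' Missingness must be confined to covariates: missing outcome, follow-up or
#' exposure-summary values are an error (they are never imputed). `simple`
#' fills with the observed mode (categorical) or median (numeric);
#' `forest` runs a chained random-forest imputation (missForest-style):
#' after a simple initialisation, each incomplete column is repeatedly
#' re-predicted from the others with a random forest until the imputed
#' values stabilise or `max_iter` is reached.
#'
#' @param cohort Cohort tibble.
#' @param method `"simple"` or `"forest"`.
#' @param seed Integer seed (forest method).
#' @param max_iter Maximum chained-imputation sweeps.
#' @param num_trees Trees per forest.
#' @param columns Columns eligible for imputation; defaults to every
#'   non-protected column with missing values.
#' @return The cohort with no remaining missing covariate values.
#' @export
impute_covariates <- function(cohort, method = c("simple", "forest"),
                              seed = 1L, max_iter = 5, num_trees = 100,
                              columns = NULL) {
  method <- match.arg(method)
  protected <- c("participant_id", "time_years", "time_months", "event",
                 "tvpa_mg", "mvpa_h_day", "lpa_h_day", "st_h_day",
                 grep("^def_", names(cohort), value = TRUE))
  present <- intersect(protected, names(cohort))
  bad <- present[map_lgl(present, function(cl) anyNA(cohort[[cl]]))]
  if (length(bad)) {
    abort(paste0("Missing values in protected column(s): ",
                 paste(bad, collapse = ", "),
                 "; outcomes and exposures are never imputed."),
          class = "frailpa_impute_error")
  }
  columns <- columns %||%
    setdiff(names(cohort)[map_lgl(names(cohort),
                                  function(cl) anyNA(cohort[[cl]]))],
            protected)
  if (!length(columns)) return(cohort)

  was_chr <- map_lgl(columns, function(cl) is.character(cohort[[cl]]))
  for (cl in columns[was_chr]) cohort[[cl]] <- factor(cohort[[cl]])

  miss_idx <- lapply(columns, function(cl) which(is.na(cohort[[cl]])))
  names(miss_idx) <- columns
  # simple initialisation
  for (cl in columns) {
    fill <- impute_simple_values(cohort[[cl]])
    if (is.factor(cohort[[cl]])) {
      cohort[[cl]][miss_idx[[cl]]] <- fill
    } else {
      cohort[[cl]][miss_idx[[cl]]] <- as.numeric(fill)
    }
  }
  if (method == "simple") return(cohort)

  set.seed(seed)
  predictors <- setdiff(names(cohort), c(protected, "fi", "fi_category",
                                         "fi_complete", "joint_group"))
  predictors <- predictors[map_lgl(predictors, function(cl) {
    v <- cohort[[cl]]
    (is.numeric(v) || is.factor(v) || is.logical(v)) && !anyNA(v)
  })]
  order_cols <- columns[order(purrr::map_int(miss_idx, length))]
  prev_change <- Inf
  for (iter in seq_len(max_iter)) {
    change <- 0
    for (cl in order_cols) {
      idx <- miss_idx[[cl]]
      if (!length(idx)) next
      rhs <- setdiff(predictors, cl)
      fml <- stats::reformulate(rhs, response = cl)
      rf <- ranger::ranger(fml, data = cohort[-idx, c(cl, rhs)],
                           num.trees = num_trees, respect.unordered.factors = TRUE,
                           seed = seed + iter, num.threads = 1)
      pred <- predict(rf, data = cohort[idx, rhs, drop = FALSE],
                      num.threads = 1)$predictions
      old <- cohort[[cl]][idx]
      cohort[[cl]][idx] <- pred
      if (is.numeric(pred)) {
        denom <- sum(as.numeric(pred)^2)
        change <- change + if (denom > 0)
          sum((as.numeric(old) - as.numeric(pred))^2) / denom else 0
      } else {
        change <- change + mean(as.character(old) != as.character(pred))
      }
    }
    if (change == 0 || change >= prev_change) break
    prev_change <- change
  }
  for (cl in columns[was_chr]) cohort[[cl]] <- as.character(cohort[[cl]])
  cohort
}

#' Configuration for the end-to-end pipeline
#'
#' @param generator A [cohort_config()] describing the synthetic cohort, or
#'   `NULL` when reading data from `cohort_path`.
#' @param cohort_path Optional CSV of an existing cohort table.
#' @param population_rates Population mortality table (tibble or CSV path);
#'   defaults to the packaged synthetic schedule.
#' @param awake_window Awake window for epoch aggregation.
#' @param exposures Exposures to analyse.
#' @param exposure_source `"epochs"` derives summaries by generating and
#'   aggregating 30-s epochs; `"summary"` trusts the per-participant summary
#'   columns already present.
#' @param exclusions Exclusion rules, in order.
#' @param impute_method `"simple"` or `"forest"`.
#' @param adjustment Adjustment covariates for all models.
#' @param bootstrap_runs Bootstrap runs for life-expectancy intervals.
#' @param spline_min_events Minimum events per spline stratum; strata under
#'   the threshold are skipped and logged.
#' @param landmark,exclude_shift_workers,complete_case,mutual_extra
#'   Sensitivity toggles: drop deaths in the first two years; drop shift
#'   workers; analyse complete cases instead of imputing; additionally
#'   mutually adjust MVPA and LPA for each other.
#' @param seed Master seed for the stochastic stages.
#' @param out_dir Output directory (created if needed).
#' @return List of class `frailpa_pipeline_config`.
#' @export
pipeline_config <- function(generator = cohort_config(n_participants = 5000),
                            cohort_path = NULL,
                            population_rates = NULL,
                            awake_window = "06:00-22:00",
                            exposures = c("tvpa", "mvpa", "lpa", "st"),
                            exposure_source = c("epochs", "summary"),
                            exclusions = c("invalid_wear", "incomplete_fi",
                                           "missing_mortality", "age_lt_45"),
                            impute_method = "simple",
                            adjustment = default_adjustment(),
                            bootstrap_runs = 1000,
                            spline_min_events = 50,
                            landmark = FALSE,
                            exclude_shift_workers = FALSE,
                            complete_case = FALSE,
                            mutual_extra = FALSE,
                            seed = 20250L,
                            out_dir = tempfile("frailpa_run_")) {
  exposure_source <- match.arg(exposure_source)
  if (is.null(population_rates)) {
    population_rates <- synthetic_population_rates()
  } else if (is.character(population_rates)) {
    population_rates <- read_population_rates(population_rates)
  } else {
    validate_population_rates(population_rates)
  }
  if (landmark) exclusions <- c(exclusions, "landmark_2yr")
  if (exclude_shift_workers) exclusions <- c(exclusions, "shift_worker")
  structure(list(generator = generator, cohort_path = cohort_path,
                 population_rates = population_rates,
                 awake_window = awake_window, exposures = exposures,
                 exposure_source = exposure_source, exclusions = exclusions,
                 impute_method = impute_method, adjustment = adjustment,
                 bootstrap_runs = bootstrap_runs,
                 spline_min_events = spline_min_events,
                 landmark = landmark,
                 exclude_shift_workers = exclude_shift_workers,
                 complete_case = complete_case, mutual_extra = mutual_extra,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "frailpa_pipeline_config")
}

le_reference_map <- function(exposure, groups) {
  # within each frailty stratum, compare against the most favourable
  # tertile: top tertile for the activity exposures, lowest for ST
  ref_t <- if (exposure == "st") "T1" else "T3"
  setNames(paste0(sub("_T[123]$", "", groups), "_", ref_t), groups)
}

#' Run the full analysis pipeline
#'
#' Executes generate (or load) -> exclusions -> frailty index -> exposure
#' aggregation -> tertiles -> missingness and imputation -> joint-group HRs,
#' spline curves, interaction tests and PH diagnostics per exposure ->
#' sex-specific life tables with bootstrap intervals, and writes every table
#' plus the exclusion log, resolved configuration and seeds to `out_dir`.
#' Re-running with the same configuration is byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all result objects and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "frailpa_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "frailpa_pipeline_error")
    })
  }

  # -- generate or load ------------------------------------------------
  truth <- NULL
  cohort <- stage("generate", {
    if (!is.null(config$cohort_path)) {
      readr::read_csv(config$cohort_path, show_col_types = FALSE)
    } else {
      sim <- generate_cohort(config$generator, epochs = FALSE)
      truth <- sim$truth
      sim$cohort
    }
  })

  # -- frailty index ---------------------------------------------------
  cohort <- stage("frailty_index", add_frailty_index(cohort))

  # -- exposures -------------------------------------------------------
  if (config$exposure_source == "epochs" && !is.null(config$generator)) {
    cohort <- stage("exposures", {
      agg <- summarise_epoch_exposures(cohort, config$generator,
                                       ids = cohort$participant_id,
                                       window = config$awake_window)
      cohort |>
        select(-dplyr::any_of(c("tvpa_mg", "mvpa_h_day", "lpa_h_day",
                                "st_h_day", "n_valid_days",
                                "weekend_covered"))) |>
        left_join(agg |> select(-"valid"), by = "participant_id") |>
        mutate(valid_wear = .data$n_valid_days >= 3 & .data$weekend_covered)
    })
  }

  # -- exclusions ------------------------------------------------------
  excl <- stage("exclusions", apply_exclusions(cohort, config$exclusions))
  cohort <- excl$cohort

  # -- tertiles --------------------------------------------------------
  tert <- stage("tertiles", add_exposure_tertiles(cohort))
  cohort <- tert$cohort

  # -- missingness and imputation -------------------------------------
  cohort <- stage("imputation", {
    cohort <- inject_missingness(cohort, config$generator$missing_rates %||%
                                   numeric(), seed = config$seed + 1L)
    if (config$complete_case) {
      cc <- complete.cases(cohort[, config$adjustment, drop = FALSE])
      cohort[cc, ]
    } else {
      impute_covariates(cohort, method = config$impute_method,
                        seed = config$seed + 2L)
    }
  })

  # -- models per exposure --------------------------------------------
  fits <- list()
  notes <- list()
  for (exp_nm in config$exposures) {
    extra <- character()
    if (config$mutual_extra && exp_nm %in% c("mvpa", "lpa")) {
      extra <- setdiff(c("mvpa_h_day", "lpa_h_day"),
                       exposure_value_col(exp_nm))
    }
    spec <- analysis_spec(exp_nm, adjustment = config$adjustment,
                          extra_adjustment = extra)
    res <- list()
    res$joint <- stage(paste0("joint_", exp_nm),
                       joint_group_hrs(cohort, spec))
    readr::write_csv(as_tibble(res$joint), out(paste0("joint_hr_", exp_nm, ".csv")))

    res$splines <- list()
    for (fc in c("robust", "pre_frail", "frail")) {
      sp <- tryCatch(
        rcs_dose_response(cohort, spec, fi_subset = fc,
                          min_events = config$spline_min_events),
        error = function(e) conditionMessage(e))
      if (is.character(sp)) {
        notes[[paste("spline", exp_nm, fc, sep = "_")]] <- sp
      } else {
        res$splines[[fc]] <- sp
        readr::write_csv(sp$curve,
                         out(paste0("spline_", exp_nm, "_", fc, ".csv")))
      }
    }

    full <- stage(paste0("lrt_full_", exp_nm),
                  fit_cox(cohort, analysis_spec(exp_nm,
                                                adjustment = config$adjustment,
                                                extra_adjustment = extra,
                                                interaction = TRUE)))
    reduced <- fit_cox(cohort, analysis_spec(exp_nm,
                                             adjustment = config$adjustment,
                                             extra_adjustment = extra))
    res$lrt <- lrt_interaction(full, reduced)
    res$reri <- tryCatch(
      reri_joint(attr(res$joint, "fit"), exposure = exp_nm,
                 seed = config$seed + 3L),
      error = function(e) {
        notes[[paste0("reri_", exp_nm)]] <<- conditionMessage(e)
        NULL
      })
    res$ph <- ph_check(reduced)
    jsonlite::write_json(
      list(lrt = as.list(res$lrt),
           reri = if (!is.null(res$reri)) lapply(res$reri, as.list),
           ph = as.list(as_tibble(res$ph))),
      out(paste0("interaction_", exp_nm, ".json")), auto_unbox = TRUE,
      digits = NA)

    # -- life expectancy per sex --------------------------------------
    res$le <- list()
    for (s in c("women", "men")) {
      le_res <- tryCatch({
        sub <- cohort |> filter(.data$sex == s) |>
          add_joint_group(exp_nm)
        sub_spec <- spec
        sub_spec$adjustment <- setdiff(spec$adjustment, "sex")
        jt <- joint_group_hrs(sub, sub_spec)
        prev <- sub |>
          count(.data$joint_group, .drop = FALSE) |>
          mutate(p = .data$n / sum(.data$n))
        gs <- group_spec(
          group = joint_group_levels(),
          prevalence = prev$p[match(joint_group_levels(),
                                    as.character(prev$joint_group))],
          hr = jt$hr[match(joint_group_levels(), jt$group)],
          coef = ifelse(joint_group_levels() == "robust_T1", NA,
                        paste0("joint_group", joint_group_levels())))
        tabs <- build_life_tables(config$population_rates, gs, sex = s)
        refs <- le_reference_map(exp_nm, gs$group)
        ci <- bootstrap_le_ci(attr(jt, "fit"), config$population_rates, gs,
                              reference = refs,
                              n_runs = config$bootstrap_runs,
                              seed = config$seed + 4L, sex = s)
        readr::write_csv(as_tibble(tabs),
                         out(paste0("life_table_", s, "_", exp_nm, ".csv")))
        readr::write_csv(as_tibble(ci),
                         out(paste0("le_diff_", s, "_", exp_nm, ".csv")))
        list(tables = tabs, ci = ci)
      }, error = function(e) conditionMessage(e))
      if (is.character(le_res)) {
        notes[[paste("le", exp_nm, s, sep = "_")]] <- le_res
      } else {
        res$le[[s]] <- le_res
      }
    }
    fits[[exp_nm]] <- res
  }

  # -- bundle ----------------------------------------------------------
  readr::write_csv(cohort |> select(-dplyr::starts_with("def_")),
                   out("cohort.csv"))
  readr::write_csv(excl$log, out("exclusion_log.csv"))
  jsonlite::write_json(tert$schemes, out("tertile_cuts.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(true_log_hr = as.list(truth$true_log_hr),
           baseline = truth$baseline),
      out("truth.json"), auto_unbox = TRUE, digits = NA)
  }
  resolved <- config
  resolved$population_rates <- NULL
  resolved$generator <- unclass(resolved$generator)
  resolved$generator$exposure_corr <-
    as.vector(resolved$generator$exposure_corr)
  yaml::write_yaml(unclass(resolved), out("config.yaml"))
  jsonlite::write_json(list(seed = config$seed,
                            generator_seed = config$generator$seed %||% NA,
                            notes = notes),
                       out("run_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, exclusion_log = excl$log,
                 tertile_cuts = tert$schemes, results = fits,
                 notes = notes, out_dir = config$out_dir))
}

#' RERI between low activity and frailty from a joint-group fit
#'
#' Uses the nine-group coefficients to form the additive-interaction
#' contrast between the high-risk exposure tertile (lowest activity, or
#' highest sedentary time) and frailty, with the robust reference-tertile
#' group as the common reference: `HR10` is the high-risk tertile among the
#' robust, `HR01` is the frail reference-tertile group, and `HR11` the frail
#' high-risk group.
#'
#' @param fit The `frailpa_cox` behind a [joint_group_hrs()] table.
#' @param exposure Exposure name (determines the high-risk tertile).
#' @param fi_level Frailty contrast level (default `"frail"`).
#' @param ... Passed to [reri()].
#' @return The [reri()] tibble.
#' @export
reri_joint <- function(fit, exposure, fi_level = "frail", ...) {
  b <- coef(fit)
  # common reference = robust x favourable tertile (T3 for activity, T1 for
  # ST); the 2x2 contrasts are linear combinations of the joint coefficients,
  # which are log HRs versus robust_T1 (itself coefficient 0).
  if (exposure == "st") {
    nms <- c(paste0("joint_grouprobust_T3"),
             paste0("joint_group", fi_level, "_T1"),
             paste0("joint_group", fi_level, "_T3"))
    # e = b_rT3; f = b_fT1; e + f + x = b_fT3
    j <- matrix(c(1, 0, 0,
                  0, 1, 0,
                  -1, -1, 1), 3, 3, byrow = TRUE)
  } else {
    nms <- c(paste0("joint_grouprobust_T3"),
             paste0("joint_group", fi_level, "_T3"),
             paste0("joint_group", fi_level, "_T1"))
    # e = -b_rT3; f = b_fT3 - b_rT3; e + f + x = b_fT1 - b_rT3
    j <- matrix(c(-1, 0, 0,
                  -1, 1, 0,
                  1, -1, 1), 3, 3, byrow = TRUE)
  }
  if (!all(nms %in% names(b))) {
    abort(paste0("Fit lacks joint-group term(s): ",
                 paste(setdiff(nms, names(b)), collapse = ", ")),
          class = "frailpa_reri_error")
  }
  b3 <- drop(j %*% b[nms])
  names(b3) <- c("e", "f", "x")
  v3 <- j %*% vcov(fit)[nms, nms] %*% t(j)
  dimnames(v3) <- list(names(b3), names(b3))
  reri(hazard_fit(b3, v3), c("e", "f", "x"), ...)
}
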