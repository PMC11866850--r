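#' Restricted-cubic-spline dose-response curve
#'
#' Fits an adjusted Cox model with the exposure entering through a restricted
#' (natural) cubic spline with four knots at the 5th, 35th, 65th and 95th
#' percentiles of the analysis sample, and returns the hazard-ratio curve
#' relative to the 5th percentile: `HR(x) = exp(f(x) - f(x_ref))` with
#' pointwise Wald 95% bands. The curve is linear in the log hazard beyond
#' the boundary knots, as the restricted basis requires.
#'
#' @param cohort Cohort tibble.
#' @param spec An [analysis_spec()]; the exposure is taken from it and its
#'   adjustment/mutual rules apply. `fi_form` other than `"none"` adds
#'   `fi_category` as a covariate unless `fi_subset` is given.
#' @param fi_subset Optional frailty category (`"robust"`, `"pre_frail"`,
#'   `"frail"`): restricts the analysis sample to that stratum, with knot
#'   percentiles computed on the stratified sample.
#' @param min_events Minimum number of events required in the analysis
#'   sample (default 50).
#' @param grid_length Number of grid points for the curve.
#' @return An object of class `frailpa_spline`: list with `knots`,
#'   `reference_x`, `curve` (tibble `x`, `loghr`, `se`, `hr`, `ci_lo`,
#'   `ci_hi`), `fit` and `exposure`.
#' @export
rcs_dose_response <- function(cohort, spec, fi_subset = NULL,
                              min_events = 50, grid_length = 200) {
  stopifnot(inherits(spec, "frailpa_spec"))
  xcol <- exposure_value_col(spec$exposure)
  data <- cohort
  if (!is.null(fi_subset)) {
    data <- data |> filter(.data$fi_category == fi_subset)
  }
  if (sum(data$event) < min_events) {
    abort(sprintf("Only %d events in the analysis sample (minimum %d).",
                  sum(data$event), min_events),
          class = "frailpa_spline_error")
  }
  x <- data[[xcol]]
  knots <- unname(quantile(x, c(0.05, 0.35, 0.65, 0.95), type = 7))
  if (anyDuplicated(knots)) {
    abort("Degenerate exposure: spline knots are not distinct.",
          class = "frailpa_spline_error")
  }
  basis <- function(v) {
    splines::ns(v, knots = knots[2:3], Boundary.knots = knots[c(1, 4)])
  }
  adj <- c(spec$adjustment, spec$mutual, spec$extra_adjustment)
  adj <- setdiff(adj, xcol)
  if (is.null(fi_subset) && spec$fi_form != "none") adj <- c("fi_category", adj)
  adj <- adj[adj %in% names(data)]
  check_no_missing(data, unique(c("time_months", "event", xcol, adj)))
  bs <- basis(x)
  colnames(bs) <- paste0("rcs", seq_len(ncol(bs)))
  mdata <- bind_cols(data, as_tibble(as.data.frame(bs)))
  check_events_per_level(mdata, adj)
  fml <- stats::reformulate(c(colnames(bs), adj),
                            response = "survival::Surv(time_months, event)")
  fit <- survival::coxph(fml, data = mdata, ties = "efron")
  cn <- colnames(bs)
  b <- coef(fit)[cn]
  v <- stats::vcov(fit)[cn, cn]

  ref_x <- knots[1]
  grid_x <- seq(min(x), max(x), length.out = grid_length)
  d <- basis(grid_x) - matrix(basis(ref_x), nrow = grid_length,
                              ncol = length(cn), byrow = TRUE)
  loghr <- drop(d %*% b)
  se <- sqrt(pmax(rowSums((d %*% v) * d), 0))
  z <- qnorm(0.975)
  curve <- tibble(x = grid_x, loghr = loghr, se = se, hr = exp(loghr),
                  ci_lo = exp(loghr - z * se), ci_hi = exp(loghr + z * se))
  structure(list(exposure = spec$exposure, fi_subset = fi_subset,
                 knots = knots, reference_x = ref_x, curve = curve,
                 fit = hazard_fit(coef(fit), stats::vcov(fit),
                                  loglik = fit$loglik[2],
                                  n_events = fit$nevent, model = fit,
                                  spec = spec),
                 basis = basis),
            class = "frailpa_spline")
}

#' Evaluate a fitted spline curve at new exposure values
#'
#' @param object A `frailpa_spline`.
#' @param x Numeric exposure values.
#' @return Tibble `x`, `loghr`, `hr` relative to the curve's reference.
#' @export
predict_spline_hr <- function(object, x) {
  cn <- paste0("rcs", 1:3)
  b <- coef(object$fit)[cn]
  d <- object$basis(x) -
    matrix(object$basis(object$reference_x), nrow = length(x),
           ncol = length(b), byrow = TRUE)
  loghr <- drop(d %*% b)
  tibble(x = x, loghr = loghr, hr = exp(loghr))
}

#' @export
print.frailpa_spline <- function(x, ...) {
  cat("<frailpa_spline>", x$exposure,
      if (!is.null(x$fi_subset)) paste0("(", x$fi_subset, ")"), "\n")
  cat("  knots:", paste(signif(x$knots, 4), collapse = ", "),
      " reference:", signif(x$reference_x, 4), "\n")
  invisible(x)
}
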