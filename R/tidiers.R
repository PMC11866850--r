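#' Tidy a Cox fit into a coefficient table
#'
#' @param x A `frailpa_cox`.
#' @param exponentiate Report hazard ratios instead of log hazard ratios.
#' @param conf_level Confidence level for the Wald interval.
#' @param ... Unused.
#' @return Tibble: `term`, `estimate`, `std_error`, `statistic`, `p_value`,
#'   `conf_low`, `conf_high`.
#' @export
tidy.frailpa_cox <- function(x, exponentiate = FALSE, conf_level = 0.95, ...) {
  b <- coef(x)
  se <- sqrt(diag(vcov(x)))
  z <- qnorm(1 - (1 - conf_level) / 2)
  out <- tibble(term = names(b), estimate = unname(b),
                std_error = unname(se),
                statistic = unname(b / se),
                p_value = 2 * pnorm(-abs(unname(b / se))),
                conf_low = unname(b - z * se),
                conf_high = unname(b + z * se))
  if (exponentiate) {
    out <- out |>
      mutate(estimate = exp(.data$estimate),
             conf_low = exp(.data$conf_low),
             conf_high = exp(.data$conf_high))
  }
  out
}

#' One-row model summary of a Cox fit
#'
#' @param x A `frailpa_cox`.
#' @param ... Unused.
#' @return Tibble: `n_events`, `n_terms`, `log_lik`, `ties`.
#' @export
glance.frailpa_cox <- function(x, ...) {
  tibble(n_events = x$n_events, n_terms = length(coef(x)),
         log_lik = x$loglik, ties = x$ties)
}

#' Forest-style plot of joint-group hazard ratios
#'
#' @param object A `frailpa_joint` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.frailpa_joint <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(fi_category = factor(.data$fi_category,
                                levels = c("robust", "pre_frail", "frail")))
  ggplot(d, aes(x = .data$tertile, y = .data$hr)) +
    geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    geom_point() +
    geom_errorbar(aes(ymin = .data$ci_lo, ymax = .data$ci_hi), width = 0.15) +
    facet_wrap(~fi_category) +
    scale_y_log10() +
    labs(x = "Exposure tertile", y = "Hazard ratio (95% CI)") +
    theme_minimal()
}

#' Dose-response curve plot
#'
#' @param object A `frailpa_spline`.
#' @param ... Unused.
#' @return A ggplot of the hazard-ratio curve with its 95% band and knots.
#' @export
autoplot.frailpa_spline <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$x, y = .data$hr)) +
    geom_ribbon(aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                fill = "grey80") +
    geom_line() +
    geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    scale_y_log10() +
    labs(x = object$exposure, y = "Hazard ratio vs 5th percentile") +
    theme_minimal()
}

#' Life-expectancy difference plot
#'
#' @param object A `frailpa_le` table from [bootstrap_le_ci()].
#' @param ... Unused.
#' @return A ggplot of years of life lost versus the reference, with
#'   bootstrap intervals.
#' @export
autoplot.frailpa_le <- function(object, ...) {
  d <- as_tibble(object) |>
    mutate(group = factor(.data$group, levels = rev(joint_group_levels())))
  ggplot(d, aes(x = .data$delta_years, y = .data$group)) +
    geom_point() +
    geom_errorbar(aes(xmin = .data$ci_lo, xmax = .data$ci_hi), width = 0.2) +
    geom_hline(yintercept = 0, linetype = 0) +
    labs(x = "Years of life lost vs reference", y = NULL) +
    theme_minimal()
}

#' Survivorship curves from life tables
#'
#' @param object A `frailpa_lifetable`.
#' @param ... Unused.
#' @return A ggplot of survivorship `l(a)` by group.
#' @export
autoplot.frailpa_lifetable <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$age, y = .data$l,
                                colour = .data$group)) +
    geom_line() +
    labs(x = "Age (years)", y = "Survivorship l(a)", colour = NULL) +
    theme_minimal()
}
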