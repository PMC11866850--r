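#' Parse an awake-window specification
#'
#' Windows are half-open clock intervals `[start, end)` written as
#' `"HH:MM-HH:MM"`; the default analysis window is 06:00 to 22:00, with
#' 07:00-21:00 and 08:00-20:00 as the usual sensitivity variants.
#'
#' @param window Window string, e.g. `"06:00-22:00"`.
#' @return A list with `start_sec` and `end_sec` (seconds since midnight)
#'   and `hours` (window length).
#' @examples
#' parse_awake_window("07:00-21:00")
#' @export
parse_awake_window <- function(window) {
  m <- regmatches(window,
                  regexec("^([0-9]{2}):([0-9]{2})-([0-9]{2}):([0-9]{2})$",
                          window))[[1]]
  if (length(m) != 5) {
    abort("Awake window must be of the form 'HH:MM-HH:MM'.",
          class = "frailpa_window_error")
  }
  v <- as.numeric(m[-1])
  start_sec <- v[1] * 3600 + v[2] * 60
  end_sec <- v[3] * 3600 + v[4] * 60
  if (start_sec >= end_sec) {
    abort("Awake window start must precede its end within one day.",
          class = "frailpa_window_error")
  }
  list(start_sec = start_sec, end_sec = end_sec,
       hours = (end_sec - start_sec) / 3600)
}

awake_window_hours <- function(window) parse_awake_window(window)$hours

#' Weekday labels used in epoch records
#' @return Character vector Mon..Sun.
#' @export
weekday_levels <- function() c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")

#' Assess wear validity from epoch records
#'
#' A day is valid when at least `min_day_fraction` of its 24 h is covered by
#' epochs; a participant's record is valid when there are at least three
#' valid days and at least one epoch falls on a Saturday or Sunday (records
#' with no data on both weekend days are invalid).
#'
#' @param epochs Epoch tibble with columns `participant_id`, `day_index`,
#'   `weekday` (factor Mon..Sun) and `epoch_start` (seconds since midnight).
#' @param min_day_fraction Fraction of the day that must be covered for a
#'   day to count as valid (default 0.75).
#' @return A tibble with one row per participant: `n_valid_days`,
#'   `weekend_covered`, `valid`.
#' @export
assess_wear_validity <- function(epochs, min_day_fraction = 0.75) {
  if (nrow(epochs) == 0) {
    return(tibble(participant_id = integer(), n_valid_days = integer(),
                  weekend_covered = logical(), valid = logical()))
  }
  day_tab <- epochs |>
    group_by(.data$participant_id, .data$day_index) |>
    summarise(frac = dplyr::n() * 30 / 86400,
              weekend = first(.data$weekday) %in% c("Sat", "Sun"),
              .groups = "drop")
  day_tab |>
    group_by(.data$participant_id) |>
    summarise(n_valid_days = sum(.data$frac >= min_day_fraction),
              weekend_covered = any(.data$weekend),
              .groups = "drop") |>
    mutate(valid = .data$n_valid_days >= 3 & .data$weekend_covered)
}

#' Aggregate 30-s epochs into per-participant exposures
#'
#' Derives the four exposure summaries over valid wear days: total volume of
#' physical activity (TVPA) as the mean ENMO over awake-window epochs pooled
#' across valid days, and MVPA/LPA/ST as mean daily hours spent in epochs
#' carrying the respective behaviour label inside the window.
#' Sleep-labelled epochs inside the window contribute to the ENMO mean (TVPA
#' is defined by clock time) but not to the behaviour hour totals.
#'
#' @param epochs Epoch tibble (`participant_id`, `day_index`, `weekday`,
#'   `epoch_start` in seconds, `enmo_mg`, `behavior`).
#' @param window Awake window string, default `"06:00-22:00"`.
#' @param min_day_fraction Valid-day coverage threshold passed to
#'   [assess_wear_validity()].
#' @return Tibble with one row per participant: `tvpa_mg`, `mvpa_h_day`,
#'   `lpa_h_day`, `st_h_day`, `n_valid_days`, `weekend_covered`, `valid`.
#' @examples
#' # sixty 30-s MVPA epochs in one day -> 0.5 h/day
#' @export
aggregate_epochs <- function(epochs, window = "06:00-22:00",
                             min_day_fraction = 0.75) {
  w <- parse_awake_window(window)
  if (nrow(epochs) == 0) {
    abort("No epochs supplied.", class = "frailpa_exposure_error")
  }
  pid <- as.integer(epochs$participant_id)
  day <- as.integer(epochs$day_index)
  key <- pid * 8L + day

  # per participant-day coverage and weekend flags
  one <- rep(1L, length(key))
  day_n <- rowsum(one, key)                 # sorted by key
  day_key <- as.integer(rownames(day_n))
  day_pid <- day_key %/% 8L
  is_weekend <- as.character(epochs$weekday) %in% c("Sat", "Sun")
  day_we <- rowsum(as.integer(is_weekend), key)[, 1] > 0
  day_ok <- day_n[, 1] * 30 / 86400 >= min_day_fraction

  per_pid_valid <- rowsum(as.integer(day_ok), day_pid)
  per_pid_we <- rowsum(as.integer(day_we), day_pid)[, 1] > 0
  pids <- as.integer(rownames(per_pid_valid))
  validity <- tibble(participant_id = pids,
                     n_valid_days = unname(per_pid_valid[, 1]),
                     weekend_covered = unname(per_pid_we)) |>
    mutate(valid = .data$n_valid_days >= 3 & .data$weekend_covered)

  # restrict to awake-window epochs on valid days
  kept <- day_ok[findInterval(key, day_key)] &
    epochs$epoch_start >= w$start_sec & epochs$epoch_start < w$end_sec
  pid_k <- pid[kept]
  beh <- as.character(epochs$behavior)[kept]
  enmo_sum <- rowsum(epochs$enmo_mg[kept], pid_k)
  n_awake <- rowsum(rep(1L, length(pid_k)), pid_k)[, 1]
  upids <- as.integer(rownames(enmo_sum))
  if (length(upids) < nrow(validity)) {
    bad <- setdiff(validity$participant_id, upids)
    abort(paste0("No awake-window epochs on valid days for participant(s): ",
                 paste(head(bad, 5), collapse = ", ")),
          class = "frailpa_exposure_error")
  }
  n_days <- rowsum(as.integer(day_ok), day_pid)[, 1]
  n_days <- n_days[match(upids, as.integer(rownames(per_pid_valid)))]
  beh_h <- function(lbl) {
    s <- rowsum(as.integer(beh == lbl), pid_k)[, 1]
    unname(s / 120 / n_days)
  }
  agg <- tibble(participant_id = upids,
                tvpa_mg = unname(enmo_sum[, 1] / n_awake),
                mvpa_h_day = beh_h("mvpa"),
                lpa_h_day = beh_h("light"),
                st_h_day = beh_h("sedentary"))
  validity |>
    left_join(agg, by = "participant_id") |>
    select("participant_id", "tvpa_mg", "mvpa_h_day", "lpa_h_day",
           "st_h_day", "n_valid_days", "weekend_covered", "valid")
}

#' Assign exposure tertiles
#'
#' Cut points sit at the 33.3rd and 66.7th percentiles of the supplied
#' analysis sample; labels `T1`/`T2`/`T3` ascend with the exposure and `T1`
#' (the first tertile) is always the reference. Ties at a cut point resolve
#' to the lower tertile (right-closed intervals).
#'
#' @param values Numeric exposure vector with at least three finite distinct
#'   values.
#' @param exposure Optional exposure name recorded in the scheme.
#' @return A list with `labels` (factor `T1`/`T2`/`T3` aligned to `values`,
#'   `NA` for non-finite inputs) and `scheme` (one-row tibble with
#'   `exposure`, `cut_lo`, `cut_hi`, `reference_tertile`).
#' @examples
#' assign_tertiles(1:9)$labels
#' @export
assign_tertiles <- function(values, exposure = NA_character_) {
  finite <- values[is.finite(values)]
  if (length(finite) < 3 || length(unique(finite)) < 3) {
    abort("Tertiles need at least three distinct finite values.",
          class = "frailpa_tertile_error")
  }
  cuts <- unname(quantile(finite, c(1, 2) / 3, type = 7))
  labels <- factor(paste0("T", 1 + (values > cuts[1]) + (values > cuts[2])),
                   levels = c("T1", "T2", "T3"))
  labels[!is.finite(values)] <- NA
  if (any(table(labels) == 0)) {
    abort("Degenerate exposure: an empty tertile on the defining sample.",
          class = "frailpa_tertile_error")
  }
  list(labels = labels,
       scheme = tibble(exposure = exposure, cut_lo = cuts[1], cut_hi = cuts[2],
                       reference_tertile = "T1"))
}

#' Add tertile columns for the four exposures
#'
#' @param cohort Cohort tibble with exposure summary columns.
#' @param exposures Named character vector mapping tertile column prefixes to
#'   exposure columns.
#' @return A list with `cohort` (tertile columns `*_tertile` added) and
#'   `schemes` (tibble of cut points, one row per exposure).
#' @export
add_exposure_tertiles <- function(cohort,
                                  exposures = c(tvpa = "tvpa_mg",
                                                mvpa = "mvpa_h_day",
                                                lpa = "lpa_h_day",
                                                st = "st_h_day")) {
  schemes <- list()
  for (nm in names(exposures)) {
    t <- assign_tertiles(cohort[[exposures[[nm]]]], exposure = nm)
    cohort[[paste0(nm, "_tertile")]] <- t$labels
    schemes[[nm]] <- t$scheme
  }
  list(cohort = as_tibble(cohort), schemes = bind_rows(schemes))
}
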