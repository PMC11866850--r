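#' Generate 30-second epoch records for cohort participants
#'
#' Emits the epoch-level accelerometer record implied by a participant's
#' exposure summaries: for each recorded wear day, 30-s epochs cover the full
#' 24 h; awake-window epochs carry behaviour labels whose daily counts match
#' the participant's quantised MVPA/LPA/ST hours (remaining awake epochs are
#' labelled sleep, e.g. naps), randomly interleaved through the window, and
#' ENMO values are behaviour-scaled lognormal draws rescaled per participant
#' so that the awake-window ENMO mean equals the participant's TVPA exactly.
#'
#' Randomness is seeded per fixed block of 250 participant ids derived from
#' the cohort seed, so the emitted epochs for a participant are identical
#' whichever subset of ids is requested.
#'
#' @param cohort Cohort tibble from [generate_cohort()].
#' @param config The [cohort_config()] used to generate the cohort.
#' @param ids Integer participant ids to emit (default: the configured
#'   epoch subset).
#' @return A long tibble: `participant_id`, `day_index`, `weekday` (factor
#'   Mon..Sun), `epoch_start` (seconds since midnight), `enmo_mg`,
#'   `behavior` (factor sleep/sedentary/light/mvpa).
#' @export
generate_epochs <- function(cohort, config, ids = NULL) {
  ids <- ids %||% seq_len(min(nrow(cohort), config$n_epoch_participants))
  ids <- sort(as.integer(ids))
  if (!all(ids %in% cohort$participant_id)) {
    abort("Requested ids not present in the cohort.",
          class = "frailpa_epoch_error")
  }
  block_size <- 250L
  blocks <- unique((ids - 1L) %/% block_size)
  out <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    b <- blocks[bi]
    block_ids <- cohort$participant_id[
      (cohort$participant_id - 1L) %/% block_size == b]
    ep <- generate_epoch_block(cohort[cohort$participant_id %in% block_ids, ],
                               config, block_index = b)
    wanted <- intersect(block_ids, ids)
    if (length(wanted) == length(block_ids)) {
      out[[bi]] <- ep
    } else {
      out[[bi]] <- ep[ep$participant_id %in% wanted, ]
    }
  }
  dplyr::bind_rows(out)
}

generate_epoch_block <- function(rows, config, block_index) {
  seed <- ((config$seed %% 1000003L) * 1009L + block_index * 7919L +
             104729L) %% 2147483647L
  set.seed(seed)
  aw <- parse_awake_window(config$awake_window)
  awake_secs <- seq(aw$start_sec, aw$end_sec - 30L, by = 30L)
  n_aw <- length(awake_secs)
  all_secs <- seq(0L, 86370L, by = 30L)
  sleep_secs <- setdiff(all_secs, awake_secs)
  n_sl <- length(sleep_secs)

  n_day <- length(all_secs)
  aw_pos <- match(awake_secs, all_secs)

  rows <- rows[order(rows$participant_id), ]
  np <- nrow(rows)
  d <- rows$n_valid_days
  counts <- cbind(mvpa = as.integer(round(rows$mvpa_h_day * 120)),
                  light = as.integer(round(rows$lpa_h_day * 120)),
                  sedentary = as.integer(round(rows$st_h_day * 120)))
  counts <- cbind(counts, sleep = n_aw - rowSums(counts))
  if (any(counts < 0)) {
    abort("Behaviour hours exceed the awake window.",
          class = "frailpa_epoch_error")
  }

  # per participant-day grid (sorted by id, then day)
  pd_pid <- rep(rows$participant_id, times = d)
  pd_day <- unlist(lapply(d, seq_len), use.names = FALSE)
  pd_wd <- ((rep(rows$wear_start_weekday, times = d) + pd_day - 2L) %% 7L) + 1L
  n_pd <- length(pd_pid)

  # behaviour codes in the awake window: 1 mvpa, 2 light, 3 sedentary,
  # 4 sleep; counts repeat each day, placement is shuffled within the day
  templates <- lapply(seq_len(np), function(i) rep.int(1:4, counts[i, ]))
  beh_aw <- unlist(lapply(seq_len(np),
                          function(i) rep.int(templates[[i]], d[i])),
                   use.names = FALSE)
  grp <- rep(seq_len(n_pd), each = n_aw)
  beh_aw <- beh_aw[order(2 * grp + runif(length(beh_aw)))]

  wts <- c(100, 35, 15, 8)
  noise <- rlnorm(length(beh_aw), meanlog = -config$enmo_noise_sdlog^2 / 2,
                  sdlog = config$enmo_noise_sdlog)
  raw <- wts[beh_aw] * noise
  pid_aw_idx <- rep(rep(seq_len(np), times = d), each = n_aw)
  tot <- rowsum(raw, pid_aw_idx)
  mean_raw <- tot[, 1] / (d * n_aw)
  scale_p <- rows$tvpa_mg / mean_raw      # awake ENMO mean == tvpa exactly
  enmo_aw <- raw * scale_p[pid_aw_idx]

  # assemble complete days in clock order: sleep-window epochs carry the
  # sleep label and a low deterministic ENMO level
  n_rows <- n_pd * n_day
  idx_aw <- rep((seq_len(n_pd) - 1L) * n_day, each = n_aw) + aw_pos
  beh_code <- rep(4L, n_rows)
  beh_code[idx_aw] <- beh_aw
  pid_day_idx <- rep(rep(seq_len(np), times = d), each = n_day)
  enmo <- 8 * scale_p[pid_day_idx]
  enmo[idx_aw] <- enmo_aw

  as_factor_codes <- function(codes, levels) {
    structure(as.integer(codes), levels = levels, class = "factor")
  }
  tibble(
    participant_id = rep(pd_pid, each = n_day),
    day_index = rep(pd_day, each = n_day),
    weekday = as_factor_codes(rep(pd_wd, each = n_day), weekday_levels()),
    epoch_start = rep(all_secs, times = n_pd),
    enmo_mg = enmo,
    behavior = as_factor_codes(5L - beh_code,
                               c("sleep", "sedentary", "light", "mvpa"))
  )
}

#' Stream epoch generation through exposure aggregation
#'
#' Generates epochs block-by-block and immediately aggregates them with
#' [aggregate_epochs()], so exposure summaries can be derived from epochs for
#' tens of thousands of participants without materialising the full epoch
#' table in memory.
#'
#' @inheritParams generate_epochs
#' @param window Awake window used for aggregation (defaults to the
#'   generator's window).
#' @param min_day_fraction Valid-day threshold for aggregation.
#' @param block_size Number of participants aggregated per pass.
#' @return The [aggregate_epochs()] summary tibble for all requested ids.
#' @export
summarise_epoch_exposures <- function(cohort, config, ids = NULL,
                                      window = config$awake_window,
                                      min_day_fraction = 0.75,
                                      block_size = 250L) {
  ids <- ids %||% seq_len(min(nrow(cohort), config$n_epoch_participants))
  ids <- sort(as.integer(ids))
  chunks <- split(ids, (seq_along(ids) - 1L) %/% block_size)
  bind_rows(lapply(chunks, function(ch) {
    aggregate_epochs(generate_epochs(cohort, config, ids = ch),
                     window = window, min_day_fraction = min_day_fraction)
  }))
}

#' Write epoch records to long-format CSV
#'
#' Epoch start times are formatted as `HH:MM:SS` clock time.
#'
#' @param epochs Epoch tibble.
#' @param path Output CSV path.
#' @export
write_epochs_csv <- function(epochs, path) {
  out <- epochs |>
    mutate(epoch_start = sprintf("%02d:%02d:%02d",
                                 .data$epoch_start %/% 3600,
                                 (.data$epoch_start %% 3600) %/% 60,
                                 .data$epoch_start %% 60))
  readr::write_csv(out, path)
  invisible(path)
}
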