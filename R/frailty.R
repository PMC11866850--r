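#' Default 49-item deficit codebook
#'
#' A structurally realistic deficit-accumulation codebook with 49 self-report
#' items spanning diagnosed conditions, pain sites, sensory and functional
#' limitations, and mental well-being. Binary items score `no = 0`,
#' `yes = 1`; ordinal items map their ordered severity levels onto equally
#' spaced scores from 0 to 1. The item list is a synthetic stand-in with the
#' same structure (item count, binary/ordinal mix, scoring rules) as the
#' standard UK-Biobank frailty-index item set, not a clone of it; it can be
#' replaced by any user codebook with [read_deficit_codebook()].
#'
#' @return A tibble with columns `item`, `kind` (`"binary"`/`"ordinal"`),
#'   `levels` (list of character vectors, ordered by severity) and `scores`
#'   (list of numeric vectors in `[0, 1]`).
#' @examples
#' cb <- default_deficit_codebook()
#' nrow(cb) # 49
#' @export
default_deficit_codebook <- function() {
  binary_items <- c(
    "diabetes", "hypertension", "angina", "heart_attack", "stroke",
    "copd", "asthma", "cancer_any", "arthritis", "osteoporosis",
    "gout", "migraine", "depression_dx", "anxiety_dx", "hearing_difficulty",
    "vision_problem", "dental_problems", "chest_pain", "leg_pain_walking",
    "back_pain", "neck_pain", "knee_pain", "hip_pain", "abdominal_pain",
    "whole_body_pain", "facial_pain", "falls_last_year", "fracture_5yr",
    "long_standing_illness", "disability_benefit", "multiple_medications",
    "wheeze", "daytime_dozing", "loneliness", "mood_swings",
    "irritability", "nervous_feelings", "sick_fatigue", "weight_loss",
    "infirmity_reported"
  )
  ordinal_items <- list(
    self_rated_health = c("excellent", "good", "fair", "poor"),
    fatigue_frequency = c("never", "several_days", "more_than_half", "nearly_daily"),
    depressed_mood = c("never", "several_days", "more_than_half", "nearly_daily"),
    tenseness = c("never", "several_days", "more_than_half", "nearly_daily"),
    sleep_difficulty = c("never", "sometimes", "usually"),
    memory_self_rated = c("good", "average", "poor"),
    mobility_limitation = c("none", "some", "severe"),
    usual_walking_pace = c("brisk", "average", "slow"),
    health_change_year = c("better_or_same", "somewhat_worse", "much_worse")
  )
  bin <- tibble(
    item = binary_items, kind = "binary",
    levels = rep(list(c("no", "yes")), length(binary_items)),
    scores = rep(list(c(0, 1)), length(binary_items))
  )
  ord <- tibble(
    item = names(ordinal_items), kind = "ordinal",
    levels = unname(ordinal_items),
    scores = purrr::map(ordinal_items,
                        ~ seq(0, 1, length.out = length(.x)), .progress = FALSE) |>
      unname()
  )
  dplyr::bind_rows(bin, ord)
}

validate_codebook <- function(codebook) {
  stopifnot(is.data.frame(codebook),
            all(c("item", "kind", "levels", "scores") %in% names(codebook)))
  purrr::walk(seq_len(nrow(codebook)), function(i) {
    s <- codebook$scores[[i]]
    l <- codebook$levels[[i]]
    if (length(s) != length(l) || any(s < 0 | s > 1)) {
      abort(sprintf("Item '%s': scores must align with levels and lie in [0, 1].",
                    codebook$item[i]), class = "frailpa_codebook_error")
    }
    if (is.unsorted(s)) {
      abort(sprintf("Item '%s': scores must be non-decreasing with severity.",
                    codebook$item[i]), class = "frailpa_codebook_error")
    }
    if (codebook$kind[i] == "binary" && !identical(sort(s), c(0, 1))) {
      abort(sprintf("Item '%s': binary items must score {0, 1}.",
                    codebook$item[i]), class = "frailpa_codebook_error")
    }
    if (min(s) != 0 || max(s) != 1) {
      abort(sprintf("Item '%s': scores must span 0 to 1.",
                    codebook$item[i]), class = "frailpa_codebook_error")
    }
  })
  invisible(codebook)
}

#' Score one deficit response
#'
#' Maps a response level onto its deficit score in `[0, 1]` according to a
#' codebook entry. Missing responses propagate as missing scores.
#'
#' @param response Character response level (or `NA`).
#' @param item A one-row slice of a deficit codebook.
#' @return Numeric score in `[0, 1]`, or `NA` for a missing response.
#' @examples
#' cb <- default_deficit_codebook()
#' code_deficit("yes", cb[cb$item == "diabetes", ])
#' @export
code_deficit <- function(response, item) {
  stopifnot(is.data.frame(item), nrow(item) == 1)
  if (length(response) != 1) abort("`response` must be a single value.")
  if (is.na(response)) return(NA_real_)
  idx <- match(as.character(response), item$levels[[1]])
  if (is.na(idx)) {
    abort(sprintf("Item '%s': undeclared response level '%s'.",
                  item$item, response),
          class = "frailpa_coding_error")
  }
  item$scores[[1]][idx]
}

#' Score all deficit responses of a cohort
#'
#' Vectorised deficit coding: every codebook item must be present as a column
#' `def_<item>` (or plain `<item>`) holding response levels. Returns a numeric
#' score matrix aligned to the codebook.
#'
#' @param data A data frame with one row per participant.
#' @param codebook A deficit codebook (default [default_deficit_codebook()]).
#' @return A numeric matrix (participants x items) of scores in `[0, 1]` with
#'   `NA` where the response was missing.
#' @export
code_deficits <- function(data, codebook = default_deficit_codebook()) {
  validate_codebook(codebook)
  cols <- ifelse(paste0("def_", codebook$item) %in% names(data),
                 paste0("def_", codebook$item), codebook$item)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols)) {
    abort(paste0("Missing deficit response columns: ",
                 paste(missing_cols, collapse = ", ")),
          class = "frailpa_coding_error")
  }
  out <- matrix(NA_real_, nrow = nrow(data), ncol = nrow(codebook),
                dimnames = list(NULL, codebook$item))
  for (i in seq_len(nrow(codebook))) {
    resp <- as.character(data[[cols[i]]])
    idx <- match(resp, codebook$levels[[i]])
    bad <- !is.na(resp) & is.na(idx)
    if (any(bad)) {
      abort(sprintf("Item '%s': undeclared response level '%s'.",
                    codebook$item[i], resp[which(bad)[1]]),
            class = "frailpa_coding_error")
    }
    out[, i] <- codebook$scores[[i]][idx]
  }
  out
}

#' Compute the frailty index from item scores
#'
#' The frailty index (FI) is the sum of deficit scores divided by the number
#' of deficits considered. By default the denominator is the full item count
#' and participants with any missing item are flagged incomplete (`fi = NA`),
#' mirroring a complete-case FI; setting `min_fraction_scored` switches to
#' dividing by the number of scored items whenever at least that fraction of
#' items is available.
#'
#' @param scores Numeric vector (one participant) or matrix (participants x
#'   items) of deficit scores in `[0, 1]`, `NA` for missing.
#' @param min_fraction_scored Optional fraction in `(0, 1]`; when supplied,
#'   `fi = sum(scores, na.rm) / n_scored` for participants with
#'   `n_scored / n_items >= min_fraction_scored`.
#' @return A tibble with columns `fi`, `fi_category` and `n_items_scored`.
#' @examples
#' s <- c(rep(1, 7), rep(0, 42))
#' compute_fi(s) # fi = 7/49, pre-frail
#' @export
compute_fi <- function(scores, min_fraction_scored = NULL) {
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  if (ncol(scores) == 0) {
    abort("`scores` must contain at least one item.", class = "frailpa_fi_error")
  }
  if (any(scores < 0 | scores > 1, na.rm = TRUE)) {
    abort("Deficit scores must lie in [0, 1].", class = "frailpa_fi_error")
  }
  n_items <- ncol(scores)
  n_scored <- rowSums(!is.na(scores))
  total <- rowSums(scores, na.rm = TRUE)
  if (is.null(min_fraction_scored)) {
    fi <- ifelse(n_scored == n_items, total / n_items, NA_real_)
  } else {
    stopifnot(min_fraction_scored > 0, min_fraction_scored <= 1)
    fi <- ifelse(n_scored / n_items >= min_fraction_scored,
                 total / n_scored, NA_real_)
  }
  tibble(fi = fi,
         fi_category = classify_fi(fi, allow_na = TRUE),
         n_items_scored = as.integer(n_scored))
}

#' Classify a frailty index value
#'
#' Cut-offs: robust `fi <= 0.12`, frailty `fi >= 0.24`, pre-frailty in
#' between. Values on the boundaries go to the outer categories (0.12 is
#' robust, 0.24 is frail).
#'
#' @param fi Numeric vector of FI values in `[0, 1]`.
#' @param allow_na Keep `NA` values as `NA` instead of erroring.
#' @return Factor with levels `robust`, `pre_frail`, `frail`.
#' @examples
#' classify_fi(c(0.12, 0.18, 0.24))
#' @export
classify_fi <- function(fi, allow_na = FALSE) {
  if (!allow_na && any(is.na(fi))) {
    abort("`fi` contains missing values.", class = "frailpa_fi_error")
  }
  if (any(fi < 0 | fi > 1, na.rm = TRUE)) {
    abort("`fi` must lie in [0, 1].", class = "frailpa_fi_error")
  }
  out <- ifelse(is.na(fi), NA_character_,
                ifelse(fi <= 0.12, "robust",
                       ifelse(fi >= 0.24, "frail", "pre_frail")))
  factor(out, levels = c("robust", "pre_frail", "frail"))
}

#' Append frailty index columns to a cohort table
#'
#' Codes all deficit responses, computes the FI and its category, and returns
#' the cohort with `fi`, `fi_category` and `fi_complete` columns appended.
#'
#' @param cohort Cohort data frame with deficit response columns.
#' @inheritParams code_deficits
#' @inheritParams compute_fi
#' @return The cohort as a tibble with FI columns added.
#' @export
add_frailty_index <- function(cohort, codebook = default_deficit_codebook(),
                              min_fraction_scored = NULL) {
  scores <- code_deficits(cohort, codebook)
  fi_tab <- compute_fi(scores, min_fraction_scored = min_fraction_scored)
  cohort <- as_tibble(cohort)
  cohort$fi <- fi_tab$fi
  cohort$fi_category <- fi_tab$fi_category
  cohort$fi_complete <- fi_tab$n_items_scored == nrow(codebook)
  cohort
}

#' Read or write a deficit codebook
#'
#' Codebooks are exchanged either as JSON (a list of items with `levels` and
#' `scores`) or as long-format CSV with columns `item`, `kind`, `level`,
#' `score` ordered by severity within item.
#'
#' @param path File path ending in `.json` or `.csv`.
#' @return For `read_deficit_codebook()`, a codebook tibble; for
#'   `write_deficit_codebook()`, the path, invisibly.
#' @export
read_deficit_codebook <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::read_json(path, simplifyVector = FALSE)
    cb <- tibble(
      item = map_chr(raw, "item"),
      kind = map_chr(raw, "kind"),
      levels = map(raw, ~ as.character(unlist(.x$levels))),
      scores = map(raw, ~ as.numeric(unlist(.x$scores)))
    )
  } else {
    long <- readr::read_csv(path, show_col_types = FALSE)
    cb <- long |>
      group_by(.data$item) |>
      summarise(kind = first(.data$kind),
                levels = list(as.character(.data$level)),
                scores = list(as.numeric(.data$score)), .groups = "drop")
  }
  validate_codebook(cb)
  cb
}

#' @rdname read_deficit_codebook
#' @param codebook A deficit codebook tibble.
#' @export
write_deficit_codebook <- function(codebook, path) {
  validate_codebook(codebook)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    items <- purrr::map(seq_len(nrow(codebook)), function(i) {
      list(item = codebook$item[i], kind = codebook$kind[i],
           levels = codebook$levels[[i]], scores = codebook$scores[[i]])
    })
    jsonlite::write_json(items, path, auto_unbox = TRUE, digits = NA)
  } else {
    long <- tidyr::unnest(
      tibble(item = codebook$item, kind = codebook$kind,
             level = codebook$levels, score = codebook$scores),
      cols = c("level", "score"))
    readr::write_csv(long, path)
  }
  invisible(path)
}
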