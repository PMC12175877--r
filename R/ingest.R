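# EMA ingest: check-in parsing, prompt-window assignment, compliance
# accounting against the scheduled two check-ins per day.

#' Assign a timestamp to its prompt window
#'
#' Windows are half-open on local clock time: AM `[06:00, 10:00)` and PM
#' `[16:00, 22:00)` by default. Every timestamp maps to exactly one of
#' `AM`, `PM` or `OUT_OF_WINDOW`.
#'
#' @param ts POSIXct (or parseable) timestamps.
#' @param config A [cohort_config()] carrying the window bounds.
#' @return Character vector of window labels.
#' @export
assign_window <- function(ts, config = cohort_config()) {
  m <- clock_minutes(parse_ts(ts))
  am <- hm_to_min(config$am_window)
  pm <- hm_to_min(config$pm_window)
  out <- rep("OUT_OF_WINDOW", length(m))
  out[m >= am[1] & m < am[2]] <- "AM"
  out[m >= pm[1] & m < pm[2]] <- "PM"
  out
}

#' Scheduled number of check-ins
#'
#' @param n_participants,n_days,per_day Non-negative counts.
#' @return Their product, e.g. 36 participants x 14 days x 2 prompts = 1008.
#' @export
expected_checkins <- function(n_participants, n_days, per_day) {
  stopifnot(n_participants >= 0, n_days >= 0, per_day >= 0)
  n_participants * n_days * per_day
}

#' Parse an EMA check-in file
#'
#' Reads the `ema.csv` dialect, validates participants against the roster and
#' item scores against the 0-100 slider range, assigns each check-in to its
#' prompt window, derives the 0-based study `day_index` from each
#' participant's first check-in date, and collapses duplicate
#' (participant, day, window) rows to the earliest. Derived scores are added:
#' `sum_score` (all 8 items), `mood_score` (items 1-5) and `anxiety_score`
#' (items 6-8). Out-of-window check-ins are retained (they are excluded from
#' the compliance numerator but usable in modelling).
#'
#' @param path `ema.csv` path.
#' @param roster Roster tibble (see [parse_roster()]).
#' @param config [cohort_config()] supplying window bounds.
#' @return Tibble of check-ins; attribute `n_duplicates_dropped` records
#'   collapsed rows.
#' @export
parse_checkins <- function(path, roster, config = cohort_config()) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(participant_id = "c",
                                                 timestamp = "c",
                                                 stress_events = "c"))
  item_cols <- paste0("item_", 1:8)
  miss <- setdiff(c("participant_id", "timestamp", item_cols), names(raw))
  if (length(miss) > 0)
    stop("ema file is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)

  unknown <- setdiff(unique(raw$participant_id), roster$participant_id)
  if (length(unknown) > 0)
    stop("unknown participants in ema file: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  # item-level missingness inside a check-in is accepted; anything present
  # must be a number in the 0-100 slider range
  for (col in item_cols) {
    v <- raw[[col]]
    vn <- suppressWarnings(as.numeric(v))
    nonnum <- which(!is.na(v) & !(is.character(v) & !nzchar(trimws(v))) &
                      is.na(vn))
    if (length(nonnum) > 0)
      stop(sprintf("malformed item score (non-numeric) in ema file column %s, row(s): %s",
                   col, paste(utils::head(nonnum, 10), collapse = ", ")),
           call. = FALSE)
    oob <- which(!is.na(vn) & (vn < 0 | vn > 100))
    if (length(oob) > 0)
      stop(sprintf("malformed item score (outside [0,100]) in ema file column %s, row(s): %s",
                   col, paste(utils::head(oob, 10), collapse = ", ")),
           call. = FALSE)
    raw[[col]] <- vn
  }

  x <- raw
  x$timestamp <- parse_ts(x$timestamp)
  if (any(is.na(x$timestamp)))
    stop("unparseable timestamps in ema file", call. = FALSE)
  x$window <- assign_window(x$timestamp, config)
  x$date <- date_of(x$timestamp)

  x <- dplyr::arrange(x, participant_id, timestamp)
  x <- dplyr::group_by(x, participant_id)
  x <- dplyr::mutate(x, day_index = as.integer(date - min(date)))
  x <- dplyr::ungroup(x)

  # duplicates in the same (participant, day, window): keep the earliest
  n_before <- nrow(x)
  in_win <- x$window %in% c("AM", "PM")
  xw <- x[in_win, ]
  xw <- dplyr::slice_min(dplyr::group_by(xw, participant_id, date, window),
                         order_by = timestamp, n = 1, with_ties = FALSE)
  xw <- dplyr::ungroup(xw)
  x <- dplyr::arrange(dplyr::bind_rows(xw, x[!in_win, ]),
                      participant_id, timestamp)
  n_dropped <- n_before - nrow(x)
  if (n_dropped > 0)
    message(n_dropped, " duplicate check-in(s) collapsed to the earliest")

  if (!"is_stress_prompt" %in% names(x)) x$is_stress_prompt <- FALSE
  if (!"stress_events" %in% names(x)) x$stress_events <- ""
  x$stress_events[is.na(x$stress_events)] <- ""

  items <- as.matrix(x[item_cols])
  x$sum_score <- rowSums(items)
  x$mood_score <- rowSums(items[, .mood_items, drop = FALSE])
  x$anxiety_score <- rowSums(items[, .anx_items, drop = FALSE])

  out <- x[, c("participant_id", "timestamp", "date", "day_index", "window",
               item_cols, "sum_score", "mood_score", "anxiety_score",
               "is_stress_prompt", "stress_events")]
  attr(out, "n_duplicates_dropped") <- n_dropped
  out
}

#' Derive parsed-check-in columns for an in-memory stream
#'
#' Adds the columns [parse_checkins()] derives (date, window, day index,
#' sum/mood/anxiety scores) to a generator check-in stream without a file
#' round trip. Used by simulation experiments; no validation or
#' deduplication is performed.
#'
#' @param checkins Generator-style check-in tibble.
#' @param config [cohort_config()] supplying window bounds.
#' @return Parsed-schema check-in tibble.
#' @export
augment_checkins <- function(checkins, config = cohort_config()) {
  x <- checkins
  x$timestamp <- parse_ts(x$timestamp)
  x$window <- assign_window(x$timestamp, config)
  x$date <- date_of(x$timestamp)
  x <- dplyr::arrange(x, participant_id, timestamp)
  x <- dplyr::group_by(x, participant_id)
  x <- dplyr::mutate(x, day_index = as.integer(date - min(date)))
  x <- dplyr::ungroup(x)
  items <- as.matrix(x[paste0("item_", 1:8)])
  x$sum_score <- rowSums(items)
  x$mood_score <- rowSums(items[, .mood_items, drop = FALSE])
  x$anxiety_score <- rowSums(items[, .anx_items, drop = FALSE])
  x
}

#' Compliance accounting against the scheduled prompts
#'
#' Computes observed in-window check-ins against the expected
#' `participants x days x prompts/day` schedule, overall and per group and
#' participant, plus the mean number of unique assessment days per participant
#' and mean check-ins per participant per day. Out-of-window check-ins do not
#' count toward the numerator.
#'
#' @param checkins Parsed, deduplicated check-ins ([parse_checkins()]).
#' @param roster Roster tibble.
#' @param config [cohort_config()] supplying `n_days` and `prompts_per_day`.
#' @return A `compliance_report` list: `expected`, `observed`, `rate`
#'   (percent, exact), `per_group`, `per_participant`,
#'   `mean_days_per_participant`, `mean_checkins_per_participant_per_day`,
#'   `mean_checkins_per_participant`, `n_unique_days`.
#' @export
compliance_summary <- function(checkins, roster, config = cohort_config()) {
  expected <- expected_checkins(nrow(roster), config$n_days,
                                config$prompts_per_day)
  if (expected == 0) stop("expected check-in count is 0", call. = FALSE)
  inw <- checkins[checkins$window %in% c("AM", "PM"), ]
  observed <- nrow(inw)

  per_part <- dplyr::summarise(
    dplyr::group_by(inw, participant_id),
    observed = dplyr::n(),
    n_days_observed = dplyr::n_distinct(date), .groups = "drop")
  per_part <- dplyr::left_join(roster[, c("participant_id", "group")],
                               per_part, by = "participant_id")
  per_part$observed[is.na(per_part$observed)] <- 0L
  per_part$n_days_observed[is.na(per_part$n_days_observed)] <- 0L
  per_part$expected <- config$n_days * config$prompts_per_day
  per_part$rate <- 100 * per_part$observed / per_part$expected

  per_group <- dplyr::summarise(
    dplyr::group_by(per_part, group),
    observed = sum(observed), expected = sum(expected),
    rate = 100 * sum(observed) / sum(expected), .groups = "drop")

  n_unique_days <- sum(per_part$n_days_observed)
  out <- list(
    expected = expected,
    observed = observed,
    rate = 100 * observed / expected,
    per_group = per_group,
    per_participant = per_part,
    n_unique_days = n_unique_days,
    mean_days_per_participant = n_unique_days / nrow(roster),
    mean_checkins_per_participant = observed / nrow(roster),
    mean_checkins_per_participant_per_day =
      if (n_unique_days > 0) observed / n_unique_days else 0)
  class(out) <- "compliance_report"
  out
}

#' @export
print.compliance_report <- function(x, ...) {
  cat(sprintf("<compliance_report> %d / %d check-ins observed (%.2f%%)\n",
              x$observed, x$expected, x$rate))
  for (i in seq_len(nrow(x$per_group)))
    cat(sprintf("  %s: %.2f%%\n", x$per_group$group[i], x$per_group$rate[i]))
  cat(sprintf("  mean days/participant %.2f; check-ins/participant/day %.2f\n",
              x$mean_days_per_participant,
              x$mean_checkins_per_participant_per_day))
  invisible(x)
}

#' Serialize a compliance report
#'
#' @param report A `compliance_report`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @export
write_compliance_report <- function(report, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) {
    readr::write_csv(report$per_participant, csv_path)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(
      expected = report$expected, observed = report$observed,
      rate = round(report$rate, 2),
      per_group = report$per_group,
      n_unique_days = report$n_unique_days,
      mean_days_per_participant = round(report$mean_days_per_participant, 2),
      mean_checkins_per_participant =
        round(report$mean_checkins_per_participant, 2),
      mean_checkins_per_participant_per_day =
        round(report$mean_checkins_per_participant_per_day, 2)),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(report)
}
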