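# Model-ready tables: the item-level long table with lagged mood/anxiety,
# weekly stress (concurrent and lagged), previous-night TST and same-day
# masked steps, plus the derived check-in / night / participant-day /
# participant level tables the model registry fits on.

#' Build the model-ready item-level long table
#'
#' One row per item response (8 per complete check-in; item rows with missing
#' scores are dropped). Items 1-5 are typed `mood`, items 6-8 `anxiety`.
#' Check-in-level covariates are attached to every item row: lagged mood
#' scores (T-1..T-3) and lag-1 anxiety score over the participant's
#' *observed* check-ins in time order (missing where unavailable), the study
#' week (days 0-6 = week 1, 7-13 = week 2), concurrent and one-week-lagged
#' stress counts, the previous night's total sleep time (main sleep
#' attributed to the calendar date of its onset; the night of day `d-1`
#' feeds day `d`), same-day sleep-masked steps, and roster covariates.
#'
#' @param checkins Parsed check-ins ([parse_checkins()]).
#' @param stress Weekly stress tibble ([parse_stress()]); may be `NULL`.
#' @param sleep Sleep episode tibble; may be `NULL`.
#' @param steps_daily Per participant-day masked step totals
#'   ([daily_steps()]); may be `NULL`.
#' @param roster Roster tibble.
#' @return Item-level tibble (class `tbl_df`).
#' @export
build_long_table <- function(checkins, stress = NULL, sleep = NULL,
                             steps_daily = NULL, roster) {
  unknown <- setdiff(unique(checkins$participant_id), roster$participant_id)
  if (length(unknown) > 0)
    stop("check-ins reference participants missing from the roster: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  ck <- dplyr::arrange(checkins, participant_id, timestamp)
  ck <- dplyr::group_by(ck, participant_id)
  ck <- dplyr::mutate(
    ck,
    checkin_index = dplyr::row_number(),
    lag1_mood = dplyr::lag(mood_score, 1),
    lag2_mood = dplyr::lag(mood_score, 2),
    lag3_mood = dplyr::lag(mood_score, 3),
    lag1_anxiety = dplyr::lag(anxiety_score, 1))
  ck <- dplyr::ungroup(ck)
  ck$week_index <- ck$day_index %/% 7L + 1L
  ck$time_of_day <- ifelse(ck$window %in% c("AM", "PM"), ck$window,
                           NA_character_)

  if (!is.null(stress) && nrow(stress) > 0) {
    s <- stress[, c("participant_id", "week_index", "n_events")]
    names(s)[3] <- "stress_n"
    ck <- dplyr::left_join(ck, s, by = c("participant_id", "week_index"))
    s_lag <- s
    names(s_lag)[3] <- "stress_n_lag"
    s_lag$week_index <- s_lag$week_index + 1L
    ck <- dplyr::left_join(ck, s_lag, by = c("participant_id", "week_index"))
  } else {
    ck$stress_n <- NA_real_
    ck$stress_n_lag <- NA_real_
  }

  if (!is.null(sleep) && nrow(sleep) > 0) {
    mains <- sleep[sleep$kind == "main_sleep", ]
    nights <- tibble::tibble(participant_id = mains$participant_id,
                             night = night_date(mains$onset),
                             tst = mains$tst_min,
                             tib = mains$tib_min)
    # if a night holds several main sleeps, the longest feeds the next day
    nights <- dplyr::slice_max(dplyr::group_by(nights, participant_id, night),
                               order_by = tib, n = 1, with_ties = FALSE)
    nights <- dplyr::ungroup(nights)
    prev <- tibble::tibble(participant_id = nights$participant_id,
                           date = nights$night + 1,
                           prev_night_tst = nights$tst)
    ck <- dplyr::left_join(ck, prev, by = c("participant_id", "date"))
  } else {
    ck$prev_night_tst <- NA_real_
  }

  if (!is.null(steps_daily) && nrow(steps_daily) > 0) {
    sd2 <- steps_daily[, c("participant_id", "date", "steps")]
    names(sd2)[3] <- "same_day_steps"
    ck <- dplyr::left_join(ck, sd2, by = c("participant_id", "date"))
  } else {
    ck$same_day_steps <- NA_real_
  }

  ck <- dplyr::left_join(
    ck, roster[, c("participant_id", "group", "age", "sex", "phq9")],
    by = "participant_id")
  ck$mdd <- as.integer(ck$group == "MDD")

  item_cols <- paste0("item_", 1:8)
  long <- tidyr::pivot_longer(ck, cols = dplyr::all_of(item_cols),
                              names_to = "item_slot", values_to = "score")
  slot_idx <- as.integer(sub("item_", "", long$item_slot))
  long$item_id <- .ema_items[slot_idx]
  long$item_type <- ifelse(slot_idx %in% .mood_items, "mood", "anxiety")
  long <- long[!is.na(long$score), ]

  long[, c("participant_id", "group", "mdd", "age", "sex", "phq9",
           "date", "day_index", "week_index", "checkin_index", "time_of_day",
           "item_id", "item_type", "score", "sum_score", "mood_score",
           "anxiety_score", "lag1_mood", "lag2_mood", "lag3_mood",
           "lag1_anxiety", "stress_n", "stress_n_lag",
           "prev_night_tst", "same_day_steps")]
}

#' Assemble every table the model registry needs
#'
#' Wraps [build_long_table()] and derives the check-in, participant-day,
#' night and participant level tables (the latter carrying nap counts,
#' within-person CoV of TST and total stress events).
#'
#' @inheritParams build_long_table
#' @param hypersomnia_min Passed to [sleep_features()].
#' @return List with elements `item`, `checkin`, `participant_day`, `night`,
#'   `participant`.
#' @export
build_model_data <- function(checkins, roster, stress = NULL, sleep = NULL,
                             steps_daily = NULL, hypersomnia_min = 600) {
  long <- build_long_table(checkins, stress, sleep, steps_daily, roster)

  ckn <- dplyr::distinct(
    long, participant_id, date, checkin_index, .keep_all = TRUE)
  ckn <- ckn[, setdiff(names(ckn), c("item_id", "item_type", "score"))]
  ckn$day_f <- factor(ckn$day_index)

  night <- NULL
  participant_sleep <- NULL
  if (!is.null(sleep) && nrow(sleep) > 0) {
    night <- dplyr::left_join(
      sleep[, c("participant_id", "onset", "offset", "tib_min", "tst_min",
                "tab_min", "kind")],
      roster[, c("participant_id", "group", "age", "sex")],
      by = "participant_id")
    night$mdd <- as.integer(night$group == "MDD")
    feats <- suppressWarnings(sleep_features(sleep, hypersomnia_min))
    participant_sleep <- feats[, c("participant_id", "n_naps", "cov_tst")]
  }

  part <- roster
  part$mdd <- as.integer(part$group == "MDD")
  if (!is.null(stress) && nrow(stress) > 0) {
    st <- dplyr::summarise(dplyr::group_by(stress, participant_id),
                           stress_total = sum(n_events), .groups = "drop")
    part <- dplyr::left_join(part, st, by = "participant_id")
    part$stress_total[is.na(part$stress_total)] <- 0
  } else {
    part$stress_total <- NA_real_
  }
  if (!is.null(participant_sleep)) {
    part <- dplyr::left_join(part, participant_sleep, by = "participant_id")
  } else {
    part$n_naps <- NA_real_
    part$cov_tst <- NA_real_
  }

  pday <- NULL
  if (!is.null(steps_daily) && nrow(steps_daily) > 0) {
    pday <- dplyr::left_join(
      steps_daily[, c("participant_id", "date", "steps")],
      roster[, c("participant_id", "group", "age", "sex")],
      by = "participant_id")
    pday$mdd <- as.integer(pday$group == "MDD")
  }

  item <- long
  item$day_f <- factor(item$day_index)
  list(item = item, checkin = ckn, participant_day = pday, night = night,
       participant = part)
}
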