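# Group x item descriptive/variability table and plot-ready time-series
# export.

#' Descriptive and variability statistics per group and item
#'
#' One row per group x (8 items + sum score): number of responses, percent
#' non-zero, mean, SD, range, skewness, RMSSD, CoV and ICC. Pooled moments
#' (mean, SD, min, max, skewness, %>0) are computed over all of the group's
#' responses; RMSSD is the within-group average of per-participant RMSSDs;
#' CoV is either the average of per-participant CoVs (default) or pooled
#' SD/mean (`cov_mode = "pooled"`); the ICC comes from the group's long
#' table via [icc()].
#'
#' @param checkins Parsed check-ins ([parse_checkins()]).
#' @param roster Roster tibble.
#' @param cov_mode `"participant_mean"` or `"pooled"`.
#' @return Tibble with 2 x 9 rows and attribute `metadata` recording the
#'   aggregation conventions.
#' @export
variability_table <- function(checkins, roster,
                              cov_mode = c("participant_mean", "pooled")) {
  cov_mode <- match.arg(cov_mode)
  x <- dplyr::left_join(checkins,
                        roster[, c("participant_id", "group")],
                        by = "participant_id")
  item_cols <- paste0("item_", 1:8)
  long <- tidyr::pivot_longer(
    x[, c("participant_id", "group", "timestamp", item_cols, "sum_score")],
    cols = dplyr::all_of(c(item_cols, "sum_score")),
    names_to = "measure", values_to = "score")
  lab <- c(stats::setNames(.ema_items, item_cols), sum_score = "sum_score")
  long$measure <- lab[long$measure]
  long <- long[order(long$participant_id, long$timestamp), ]

  rows <- list()
  for (g in c("control", "MDD")) {
    for (ms in c(.ema_items, "sum_score")) {
      d <- long[long$group == g & long$measure == ms & !is.na(long$score), ]
      per_part <- split(d, d$participant_id)
      p_rmssd <- suppressWarnings(
        vapply(per_part, function(p) rmssd(p$score), numeric(1)))
      p_cov <- suppressWarnings(
        vapply(per_part, function(p) coef_variation(p$score), numeric(1)))
      cov_val <- if (cov_mode == "pooled") {
        suppressWarnings(coef_variation(d$score))
      } else {
        if (all(is.na(p_cov))) NA_real_ else mean(p_cov, na.rm = TRUE)
      }
      icc_val <- if (length(unique(d$participant_id)) < 2) {
        warning(sprintf("icc flagged for group %s (%s): < 2 participants", g, ms),
                call. = FALSE)
        NA_real_
      } else suppressWarnings(as.numeric(icc(d$score, d$participant_id)))
      rows[[length(rows) + 1]] <- tibble::tibble(
        item = ms, group = g, n_responses = nrow(d),
        pct_nonzero = 100 * mean(d$score > 0),
        mean = mean(d$score), sd = stats::sd(d$score),
        min = min(d$score), max = max(d$score),
        skewness = suppressWarnings(skewness(d$score)),
        rmssd = if (all(is.na(p_rmssd))) NA_real_ else
          mean(p_rmssd, na.rm = TRUE),
        cov = cov_val,
        icc = icc_val)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "metadata") <- list(
    cov_mode = cov_mode,
    rmssd_aggregation = "participant_mean",
    icc_estimator = "reml_random_intercept",
    within_person_share = "1 - icc")
  out
}

#' Plot-ready long time series of sum scores
#'
#' One row per check-in with a sequential per-participant index, the raw or
#' person-mean-centered sum score, and per-participant mean and +/-1 SD
#' reference values (for raw data the person's own mean/SD; for centered data
#' the mean reference is 0).
#'
#' @param checkins Parsed check-ins.
#' @param roster Roster (for the group column).
#' @param centered Center each participant's scores on their own mean?
#' @return Tibble with columns participant_id, group, checkin_index,
#'   sum_score, p_mean, p_sd_lo, p_sd_hi.
#' @export
export_timeseries <- function(checkins, roster, centered = FALSE) {
  x <- dplyr::left_join(checkins, roster[, c("participant_id", "group")],
                        by = "participant_id")
  x <- dplyr::arrange(x, participant_id, timestamp)
  x <- dplyr::group_by(x, participant_id)
  x <- dplyr::mutate(
    x,
    checkin_index = dplyr::row_number(),
    p_raw_mean = mean(sum_score, na.rm = TRUE),
    p_sd = stats::sd(sum_score, na.rm = TRUE))
  x <- dplyr::ungroup(x)
  if (centered) {
    x$sum_score <- group_mean_center(x$sum_score, x$participant_id)
    x$p_mean <- 0
  } else {
    x$p_mean <- x$p_raw_mean
  }
  x$p_sd_lo <- x$p_mean - x$p_sd
  x$p_sd_hi <- x$p_mean + x$p_sd
  x[, c("participant_id", "group", "checkin_index", "sum_score",
        "p_mean", "p_sd_lo", "p_sd_hi")]
}
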