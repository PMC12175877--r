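# Shared fixtures, built in code at test time.

# small cohort for fast structural tests
small_config <- function(seed = 1, ...) {
  cohort_config(n_mdd = 4, n_control = 3, n_days = 5, seed = seed, ...)
}

# quiet EMA-only config: mid-scale means, no diurnal/stress/zero-inflation,
# so clipping and state contrasts are inert
quiet_config <- function(seed = 1, rho = 0.3, ...) {
  cohort_config(
    item_means_mdd = rep(50, 8), item_means_ctrl = rep(50, 8),
    item_sd_within = rep(10, 8), between_person_sd = rep(8, 8),
    ar1_rho = rho, diurnal_effect_mdd = 0, zero_inflation_ctrl = 0,
    stress_rate_weekly = c(MDD = 0, control = 0), stress_effect = 0,
    miss_prob = 0, seed = seed, ...)
}

checkin_scores <- function(cohort) {
  items <- as.matrix(cohort$checkins[paste0("item_", 1:8)])
  grp <- cohort$roster$group[match(cohort$checkins$participant_id,
                                   cohort$roster$participant_id)]
  list(items = items, sum = rowSums(items), group = grp)
}

# write a sleep JSON from a list of episodes (each: start, end, levels)
write_sleep_json <- function(episodes, path) {
  jsonlite::write_json(episodes, path, auto_unbox = TRUE)
  path
}

# minimal parsed-checkin tibble builder for variability tests
make_checkins <- function(participant_id, scores_by_item, start_hour = 7) {
  n <- length(scores_by_item[[1]])
  ts <- as.POSIXct("2024-01-08", tz = "UTC") + (seq_len(n) - 1) * 43200 +
    start_hour * 3600
  ck <- tibble::tibble(participant_id = participant_id, timestamp = ts,
                       date = as.Date(ts, tz = "UTC"),
                       day_index = as.integer((seq_len(n) - 1) %/% 2),
                       window = rep(c("AM", "PM"), length.out = n))
  for (j in 1:8) ck[[paste0("item_", j)]] <- scores_by_item[[j]]
  items <- as.matrix(ck[paste0("item_", 1:8)])
  ck$sum_score <- rowSums(items)
  ck$mood_score <- rowSums(items[, 1:5, drop = FALSE])
  ck$anxiety_score <- rowSums(items[, 6:8, drop = FALSE])
  ck$is_stress_prompt <- FALSE
  ck$stress_events <- ""
  ck
}

# brute-force oracles, kept deliberately independent of the implementation
oracle_rmssd <- function(x) {
  s <- 0
  for (i in 2:length(x)) s <- s + (x[i] - x[i - 1])^2
  sqrt(s / (length(x) - 1))
}
oracle_skewness <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  m3 <- sum((x - m)^3) / n
  m3 / m2^(3 / 2)
}
oracle_cov <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1)) / m
}
# balanced one-way ANOVA moment estimator of the ICC
oracle_icc_balanced <- function(x, id) {
  k <- unique(table(id))
  stopifnot(length(k) == 1)
  m <- tapply(x, id, mean)
  n <- length(m)
  msb <- k * sum((m - mean(x))^2) / (n - 1)
  msw <- sum((x - m[id])^2) / (n * (k - 1))
  vb <- max(0, (msb - msw) / k)
  vb / (vb + msw)
}
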