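make_bundle <- function(seed = 19, cfg = small_config(seed = seed)) {
  co <- generate_cohort(cfg)
  dir <- file.path(tempdir(), paste0("mb", seed))
  write_fixture_files(co, dir)
  roster <- parse_roster(file.path(dir, "roster.csv"))
  ck <- parse_checkins(file.path(dir, "ema.csv"), roster, cfg)
  st <- parse_stress(file.path(dir, "stress.csv"), roster)
  unlink(dir, recursive = TRUE)
  masked <- mask_sleep_steps(co$steps, co$sleep)
  ds <- daily_steps(masked, roster)
  list(cohort = co, roster = roster, checkins = ck, stress = st,
       daily = ds,
       bundle = build_model_data(ck, roster, st, co$sleep, ds))
}

test_that("the long table has 8 item rows per check-in with correct typing", {
  mb <- make_bundle(19)
  long <- build_long_table(mb$checkins, mb$stress, mb$cohort$sleep,
                           mb$daily, mb$roster)
  expect_equal(nrow(long), 8 * nrow(mb$checkins))
  expect_equal(sort(unique(long$item_id)), sort(c("sad", "bothered",
                                                  "interest", "energy", "appetite", "tense", "anxious", "worry")))
  expect_equal(unique(long$item_type[long$item_id == "sad"]), "mood")
  expect_equal(unique(long$item_type[long$item_id == "worry"]), "anxiety")
  # mood items 1-5, anxiety items 6-8
  expect_equal(sum(long$item_type == "mood"), 5 * nrow(mb$checkins))

  # first check-in of each participant: all lag columns missing
  first <- long[long$checkin_index == 1, ]
  expect_true(all(is.na(first$lag1_mood)))
  expect_true(all(is.na(first$lag1_anxiety)))
  # lags refer to the immediately preceding observed check-in
  one <- long[long$participant_id == long$participant_id[1] &
                long$item_id == "sad", ]
  one <- one[order(one$checkin_index), ]
  expect_equal(one$lag1_mood[-1], one$mood_score[-nrow(one)])

  # week-2 rows carry week-1 stress in the lagged column
  wk2 <- long[long$week_index == 2 & !is.na(long$stress_n_lag), ]
  if (nrow(wk2) > 0) {
    st <- mb$stress
    for (i in utils::head(seq_len(nrow(wk2)), 20)) {
      truth <- st$n_events[st$participant_id == wk2$participant_id[i] &
                             st$week_index == 1]
      expect_equal(wk2$stress_n_lag[i], truth)
    }
  }
  expect_error(build_long_table(mb$checkins, roster = mb$roster[-1, ]),
               "missing from the roster")
})

test_that("previous-night TST joins on the onset-date convention", {
  mb <- make_bundle(23)
  long <- build_long_table(mb$checkins, mb$stress, mb$cohort$sleep,
                           mb$daily, mb$roster)
  mains <- mb$cohort$sleep[mb$cohort$sleep$kind == "main_sleep", ]
  pid <- mains$participant_id[1]
  # a day with a previous-night main sleep carries that episode's TST
  rows <- long[long$participant_id == pid & !is.na(long$prev_night_tst), ]
  expect_gt(nrow(rows), 0)
  i <- 1
  cand <- mains[mains$participant_id == pid, ]
  onset_night <- as.Date(format(cand$onset, "%Y-%m-%d")) -
    as.integer(format(cand$onset, "%H") < "12")
  match_ep <- cand[onset_night == rows$date[i] - 1, ]
  expect_true(rows$prev_night_tst[i] %in% match_ep$tst_min)
})

test_that("partial eta squared follows the F-statistic identity", {
  expect_equal(partial_eta_squared(0, 1, 100), 0)
  expect_equal(partial_eta_squared(10, 1, 100), 10 / 110)
  expect_gt(partial_eta_squared(1e9, 1, 100), 0.9999)
  expect_equal(partial_eta_squared(c(0, 10), c(1, 1), c(50, 100)),
               c(0, 10 / 110))
})

test_that("balanced single-intercept fits match the cluster-means OLS oracle", {
  # balanced clusters, between-cluster predictor: GLS reduces to OLS on
  # cluster means
  set.seed(61)
  n_cl <- 12; k <- 9
  x <- rep(stats::rnorm(n_cl), each = k)
  cl <- rep(sprintf("c%02d", 1:n_cl), each = k)
  y <- 2 + 3 * x + rep(stats::rnorm(n_cl, 0, 1), each = k) +
    stats::rnorm(n_cl * k, 0, 0.5)
  d <- data.frame(y = y, x = x, cl = cl)
  fit <- fit_lmm(model_spec("toy", "y ~ x + (1 | cl)"), d)
  means <- aggregate(cbind(y, x) ~ cl, data = d, FUN = mean)
  ols <- stats::lm(y ~ x, data = means)
  expect_equal(unname(fit$coefficients$estimate),
               unname(stats::coef(ols)), tolerance = 1e-6)
  expect_lte(fit$r2_marginal, fit$r2_conditional)
  expect_false(fit$degenerate)
})

test_that("estimates are invariant to row shuffling", {
  mb <- make_bundle(29)
  d <- mb$bundle$checkin
  spec <- model_spec("m", paste("sum_score ~ mdd + age + sex +",
                                "(1 | participant_id)"), "checkin")
  f1 <- fit_lmm(spec, d)
  set.seed(1)
  f2 <- fit_lmm(spec, d[sample(nrow(d)), ])
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-8)
})

test_that("a zero-variance response yields a flagged degenerate result", {
  d <- data.frame(y = rep(0, 40), x = stats::rnorm(40),
                  g = rep(letters[1:4], each = 10))
  res <- fit_lmm(model_spec("degen", "y ~ x + (1 | g)"), d)
  expect_true(res$degenerate)
  expect_true(all(res$coefficients$estimate == 0))
})

test_that("the random-term screen retains real structure and drops absent terms", {
  # strong participant intercepts, no day-level variance
  keep_part <- drop_day <- logical(8)
  for (s in seq_len(8)) {
    set.seed(700 + s)
    n <- 24; k <- 20
    d <- data.frame(
      score = rep(stats::rnorm(n, 0, 8), each = k) + stats::rnorm(n * k, 0, 4),
      participant_id = rep(sprintf("p%02d", 1:n), each = k),
      day_f = factor(rep(rep(1:(k / 2), each = 2), n)),
      item_type = rep(c("mood", "anxiety"), n * k / 2),
      time_of_day = rep(c("AM", "PM"), n * k / 2))
    rt <- random_effect_test(d)
    expect_true(all(rt$lrt >= -1e-8))
    keep_part[s] <- rt$keep[rt$term == "participant_id"]
    drop_day[s] <- !rt$keep[rt$term == "participant_id:day_f"]
  }
  expect_true(all(keep_part))
  expect_gte(sum(drop_day), 7)
  expect_error(random_effect_test(data.frame(score = 1:10)),
               "non-nested")
})

test_that("the registry fits every specification and survives missing inputs", {
  mb <- make_bundle(31)
  reg <- run_registry(mb$bundle)
  expect_equal(length(reg), 16)
  expect_named(reg, c("m0_unconditioned", "m1_mdd_main",
                      "m2_mdd_interactions", "m3_phq9_convergence",
                      "m4_mood_anxiety", "m5_mood_anxiety_lag1",
                      "m6_mood_autoregressive", "m7_stress",
                      "m7b_stress_group_lm", "m8a_steps_mdd",
                      "m8b_score_steps", "m9a_tst_mdd", "m9b_tib_mdd",
                      "m9c_naps_mdd", "m9d_covtst_mdd",
                      "m9e_score_prev_tst"))
  fitted <- vapply(reg, function(r) is.na(r$error), TRUE)
  expect_true(all(fitted))
  expect_equal(reg$m7b_stress_group_lm$method, "lm")
  expect_equal(reg$m9d_covtst_mdd$method, "lm")
  # marginal R2 never exceeds conditional R2
  r2m <- vapply(reg, `[[`, 1, "r2_marginal")
  r2c <- vapply(reg, `[[`, 1, "r2_conditional")
  expect_true(all(r2m <= r2c + 1e-12, na.rm = TRUE))
  # CIs bracket their estimates
  rr <- registry_results(reg)
  ok <- !is.na(rr$estimate) & !is.na(rr$ci_low)
  expect_true(all(rr$ci_low[ok] <= rr$estimate[ok] &
                    rr$estimate[ok] <= rr$ci_high[ok]))
  expect_true(all(rr$eta_p_sq >= 0 & rr$eta_p_sq <= 1, na.rm = TRUE))
  # the random screen ran on the unconditioned model
  expect_s3_class(reg$m0_unconditioned$random_test, "tbl_df")

  # without wearable tables the sleep/step models are flagged, not dropped
  b2 <- build_model_data(mb$checkins, mb$roster, mb$stress)
  reg2 <- run_registry(b2)
  expect_equal(length(reg2), 16)
  expect_match(reg2$m9a_tst_mdd$error, "unavailable")
  expect_true(is.na(reg2$m1_mdd_main$error))
})

test_that("the MDD group contrast is recovered at the generator scale", {
  # the sum-score group difference implied by the config reappears in the
  # m1-style mixed model
  cfg <- recovery_config(effect_sum = 120, seed = 77)
  co <- generate_cohort(cfg, components = "ema")
  dir <- file.path(tempdir(), "rec")
  write_fixture_files(co, dir)
  roster <- parse_roster(file.path(dir, "roster.csv"))
  ck <- parse_checkins(file.path(dir, "ema.csv"), roster, cfg)
  unlink(dir, recursive = TRUE)
  bundle <- build_model_data(ck, roster)
  fit <- fit_lmm(model_spec(
    "sum", paste("sum_score ~ mdd + age + sex + (1 | participant_id) +",
                 "(1 | participant_id:day_f)"), "checkin"), bundle$checkin)
  est <- fit$coefficients[fit$coefficients$coef == "mdd", ]
  expect_lt(abs(est$estimate - 120), 4 * est$se)
})
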