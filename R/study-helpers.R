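# Helpers that define the package's standard simulation experiments and the
# worked compliance example.

#' Configuration for parameter-recovery experiments
#'
#' A neutral mid-scale configuration for recovery simulations: both groups
#' share flat item means (no clipping pressure, no zero-inflation, no
#' diurnal or stress terms), and a known group effect is injected on the
#' sum-score scale by shifting every case item mean by `effect_sum / 8`.
#' With `effect_sum = 0` the MDD coefficient's null behaviour (type-I error)
#' can be measured; with a positive value, CI coverage of the injected
#' effect.
#'
#' @param effect_sum Injected MDD effect on the 0-800 sum-score scale.
#' @param seed Seed.
#' @param n_mdd,n_control,n_days Design; defaults mirror the study design.
#' @return A [cohort_config()].
#' @export
recovery_config <- function(effect_sum = 0, seed = 1L, n_mdd = 23,
                            n_control = 13, n_days = 14) {
  base <- rep(40, 8)
  cohort_config(
    n_mdd = n_mdd, n_control = n_control, n_days = n_days,
    item_means_mdd = base + effect_sum / 8,
    item_means_ctrl = base,
    item_sd_within = rep(12, 8),
    between_person_sd = rep(10, 8),
    ar1_rho = 0.3,
    diurnal_effect_mdd = 0,
    zero_inflation_ctrl = 0,
    stress_rate_weekly = c(MDD = 0, control = 0),
    stress_effect = 0,
    miss_prob = 0.084,
    seed = seed)
}

#' Group-effect recovery experiment
#'
#' Repeatedly simulates a cohort under [recovery_config()] and fits the
#' sum-score group model (`sum_score ~ mdd + age + sex` with participant and
#' day-within-participant random intercepts), collecting the MDD estimate,
#' Wald 95% CI and p-value per seed. With `effect_sum = 0` the rejection
#' rate estimates the type-I error of the MDD test; with a non-zero value
#' the CI coverage of the injected effect can be measured.
#'
#' @param n_seeds Number of simulated cohorts.
#' @param effect_sum Injected MDD effect (sum-score units).
#' @param base_seed Base seed the per-replicate seeds derive from.
#' @return Tibble with one row per seed: estimate, ci_low, ci_high, p,
#'   singular.
#' @export
recovery_experiment <- function(n_seeds = 200, effect_sum = 0,
                                base_seed = 1) {
  spec <- model_spec(
    "recovery",
    paste("sum_score ~ mdd + age + sex + (1 | participant_id) +",
          "(1 | participant_id:day_f)"), "checkin")
  rows <- lapply(seq_len(n_seeds), function(s) {
    seed <- derive_seed(base_seed, sprintf("recovery/%s/%d", effect_sum, s))
    cfg <- recovery_config(effect_sum = effect_sum, seed = seed)
    co <- generate_cohort(cfg, components = "ema")
    ck <- augment_checkins(co$checkins, cfg)
    bundle <- build_model_data(ck, co$roster)
    fit <- fit_lmm(spec, bundle$checkin, effects = FALSE)
    est <- fit$coefficients[fit$coefficients$coef == "mdd", ]
    tibble::tibble(seed = s, estimate = est$estimate, ci_low = est$ci_low,
                   ci_high = est$ci_high, p = est$p, singular = fit$singular)
  })
  dplyr::bind_rows(rows)
}

#' Diurnal-interaction sign-recovery experiment
#'
#' Simulates cohorts under the default study configuration (whose only
#' time-of-day structure is a case-only AM elevation) and fits the
#' interaction model (item score on MDD x time-of-day and MDD x item-type
#' with the retained random structure), collecting the MDD x time-of-day
#' coefficient per seed. Under an AM elevation in cases the PM interaction
#' coefficient is negative.
#'
#' @param n_seeds Number of simulated cohorts.
#' @param base_seed Base seed.
#' @return Tibble with one row per seed: estimate, p.
#' @export
diurnal_sign_experiment <- function(n_seeds = 100, base_seed = 1) {
  spec <- model_registry()$m2_mdd_interactions
  rows <- lapply(seq_len(n_seeds), function(s) {
    seed <- derive_seed(base_seed, sprintf("diurnal/%d", s))
    cfg <- cohort_config(seed = seed)
    co <- generate_cohort(cfg, components = "ema")
    ck <- augment_checkins(co$checkins, cfg)
    bundle <- build_model_data(ck, co$roster)
    fit <- fit_lmm(spec, bundle$item, effects = FALSE)
    est <- fit$coefficients[fit$coefficients$term == "mdd:time_of_day", ]
    tibble::tibble(seed = s, estimate = est$estimate, p = est$p)
  })
  dplyr::bind_rows(rows)
}

#' Group-direction experiment
#'
#' Simulates EMA and sleep streams under the default study configuration and
#' records, per seed, whether the case group shows the expected ordering on
#' each contrast: higher sum-score mean, higher within-person CoV of total
#' sleep time, more naps, and lower total sleep time than controls.
#'
#' @param n_seeds Number of simulated cohorts.
#' @param base_seed Base seed.
#' @return Tibble with one logical column per contrast and one row per seed.
#' @export
direction_experiment <- function(n_seeds = 100, base_seed = 1) {
  rows <- lapply(seq_len(n_seeds), function(s) {
    seed <- derive_seed(base_seed, sprintf("direction/%d", s))
    cfg <- cohort_config(seed = seed)
    co <- generate_cohort(cfg, components = c("ema", "sleep"))
    ck <- augment_checkins(co$checkins, cfg)
    grp <- co$roster$group[match(ck$participant_id, co$roster$participant_id)]
    sum_dir <- mean(ck$sum_score[grp == "MDD"]) >
      mean(ck$sum_score[grp == "control"])
    fs <- suppressWarnings(sleep_features(co$sleep))
    g <- co$roster$group[match(fs$participant_id, co$roster$participant_id)]
    tibble::tibble(
      seed = s,
      sum_score_higher = sum_dir,
      cov_tst_higher = mean(fs$cov_tst[g == "MDD"], na.rm = TRUE) >
        mean(fs$cov_tst[g == "control"], na.rm = TRUE),
      naps_more = sum(fs$n_naps[g == "MDD"]) / sum(g == "MDD") >
        sum(fs$n_naps[g == "control"]) / sum(g == "control"),
      tst_lower = mean(fs$tst_mean[g == "MDD"]) <
        mean(fs$tst_mean[g == "control"]))
  })
  dplyr::bind_rows(rows)
}

#' Worked compliance-accounting example
#'
#' Deterministically constructs a check-in table with the headline
#' feasibility arithmetic of a 36-participant, 14-day, twice-daily design:
#' 923 observed in-window check-ins over 486 unique participant-days
#' (18 participants with 13 days / 26 check-ins; 5 with 14 days / 26; 13
#' with 14 days / 25), against 1008 scheduled prompts.
#'
#' @return List with `checkins` (parsed schema) and `roster`, ready for
#'   [compliance_summary()].
#' @export
compliance_fixture <- function() {
  n_days_obs <- c(rep(13L, 18), rep(14L, 5), rep(14L, 13))
  n_obs <- c(rep(26L, 18), rep(26L, 5), rep(25L, 13))
  ids <- sprintf("4%04d", seq_len(36))
  roster <- tibble::tibble(
    participant_id = ids,
    group = c(rep("MDD", 23), rep("control", 13)),
    age = 18L, sex = "F", phq9 = 5L, gad7 = 4L)

  rows <- list()
  for (i in seq_len(36)) {
    nd <- n_days_obs[i]
    no <- n_obs[i]
    n_double <- no - nd        # days with both prompts answered
    day <- rep(seq_len(nd) - 1L, times = c(rep(2L, n_double),
                                           rep(1L, nd - n_double)))
    win <- unlist(lapply(c(rep(2L, n_double), rep(1L, nd - n_double)),
                         function(k) if (k == 2) c("AM", "PM") else "AM"))
    hour <- ifelse(win == "AM", 7L, 17L)
    ts <- as.POSIXct(.study_start, tz = "UTC") + day * 86400 + hour * 3600
    rows[[i]] <- tibble::tibble(
      participant_id = ids[i], timestamp = ts, date = date_of(ts),
      day_index = day, window = win)
  }
  ck <- dplyr::bind_rows(rows)
  for (j in 1:8) ck[[paste0("item_", j)]] <- 10
  ck$sum_score <- 80
  ck$mood_score <- 50
  ck$anxiety_score <- 30
  ck$is_stress_prompt <- FALSE
  ck$stress_events <- ""
  list(checkins = ck, roster = roster)
}
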