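# Cohort configuration: the study-design knobs of the synthetic generator.

# Item order fixed across the package: items 1-5 measure mood, 6-8 anxiety.
.ema_items <- c("sad", "bothered", "interest", "energy", "appetite",
                "tense", "anxious", "worry")
.mood_items <- 1:5
.anx_items <- 6:8

# Defaults approximate the per-item descriptive scale of a two-week,
# twice-daily adolescent EMA study (marginal means/SDs and between-person
# variance shares per group). Order follows .ema_items.
.default_means_mdd <- c(28.71, 35.97, 32.14, 46.04, 41.65, 30.73, 36.10, 31.27)
.default_means_ctrl <- c(4.38, 4.94, 2.17, 8.43, 4.23, 6.98, 9.77, 5.50)
.default_sd_total <- c(17.01, 20.07, 18.38, 22.70, 20.38, 20.22, 19.91, 18.05)
.default_icc <- c(0.59, 0.56, 0.50, 0.50, 0.58, 0.54, 0.55, 0.57)

.stress_events <- c(
  "argued_friend_family", "not_allowed", "bad_grade", "parents_arguing",
  "family_illness", "family_arrested", "teased_threatened", "teased_other",
  "embarrassed", "negative_comment_looks", "excluded_event",
  "disciplined_suspended")

#' Build a synthetic cohort configuration
#'
#' Collects every parameter of the synthetic study generator: design (group
#' sizes, days, prompt windows), EMA response model (marginal item means per
#' group, within/between-person SDs, AR(1) persistence, case-only diurnal
#' contrast, control zero-inflation), weekly stress process, group-specific
#' sleep timing/duration/nap behaviour, and daily step targets.
#'
#' Configured item means are *marginal* means: diurnal and stress effects are
#' applied as centered contrasts and latent means are moment-matched through
#' the `[0, 100]` slider clipping, so generated marginals track the
#' configuration.
#'
#' @param n_mdd,n_control Participants per group.
#' @param n_days Study days (>= 2).
#' @param prompts_per_day Scheduled check-ins per day (the design uses 2).
#' @param am_window,pm_window Prompt windows as `c(start, end)` "HH:MM"
#'   clock-time strings; half-open `[start, end)`.
#' @param miss_prob Per-prompt probability of a missed check-in (MCAR).
#' @param item_means_mdd,item_means_ctrl Length-8 marginal item score means
#'   (0-100), ordered sad, bothered, interest, energy, appetite, tense,
#'   anxious, worry.
#' @param item_sd_within Length-8 within-person (momentary) SDs.
#' @param between_person_sd Length-8 between-person intercept SDs.
#' @param ar1_rho Within-person lag-1 autocorrelation in `[0, 1)` on the
#'   ordered prompt sequence.
#' @param diurnal_effect_mdd AM-minus-PM item-score contrast for cases
#'   (score units; applied as +/- half to keep marginals fixed).
#' @param zero_inflation_ctrl Probability a control item response is exactly 0.
#' @param item_corr_between Loading of the shared person-level severity factor
#'   across item intercepts (induces item co-variation between persons).
#' @param item_corr_within Fraction of within-person variance shared across
#'   the 8 items of one check-in.
#' @param stress_rate_weekly Named vector `c(MDD=, control=)` of expected
#'   checked stress events per week.
#' @param stress_effect Item-score units added during stress weeks (centered
#'   at the expected stress-week rate).
#' @param sleep Per-group list with `onset_mean_noon_min`, `onset_sd_noon_min`
#'   (minutes from noon), `tst_mean_min`, `tst_sd_min` (main-sleep total sleep
#'   time), `nap_rate_per_day`, and `nap_dur_range_min` (`c(lo, hi)`, < 180).
#' @param steps_daily_mean Named vector of target mean daily (waking) steps.
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_mdd = 23, n_control = 13, n_days = 14, prompts_per_day = 2,
    am_window = c("06:00", "10:00"), pm_window = c("16:00", "22:00"),
    miss_prob = 0.084,
    item_means_mdd = .default_means_mdd,
    item_means_ctrl = .default_means_ctrl,
    item_sd_within = .default_sd_total * sqrt(1 - .default_icc),
    between_person_sd = .default_sd_total * sqrt(.default_icc),
    ar1_rho = 0.3,
    diurnal_effect_mdd = 2.5,
    zero_inflation_ctrl = 0.7,
    item_corr_between = 0.7,
    item_corr_within = 0.4,
    stress_rate_weekly = c(MDD = 2.0, control = 1.35),
    stress_effect = 3,
    sleep = list(
      MDD = list(onset_mean_noon_min = 660, onset_sd_noon_min = 200,
                 tst_mean_min = 370, tst_sd_min = 90,
                 nap_rate_per_day = 0.57, nap_dur_range_min = c(30, 150)),
      control = list(onset_mean_noon_min = 660, onset_sd_noon_min = 120,
                     tst_mean_min = 420, tst_sd_min = 70,
                     nap_rate_per_day = 0.084, nap_dur_range_min = c(30, 150))),
    steps_daily_mean = c(MDD = 5828.64, control = 7088.47),
    seed = 1L) {
  cfg <- list(
    n_mdd = n_mdd, n_control = n_control, n_days = n_days,
    prompts_per_day = prompts_per_day,
    am_window = am_window, pm_window = pm_window,
    miss_prob = miss_prob,
    item_means_mdd = unname(item_means_mdd),
    item_means_ctrl = unname(item_means_ctrl),
    item_sd_within = unname(item_sd_within),
    between_person_sd = unname(between_person_sd),
    ar1_rho = ar1_rho, diurnal_effect_mdd = diurnal_effect_mdd,
    zero_inflation_ctrl = zero_inflation_ctrl,
    item_corr_between = item_corr_between,
    item_corr_within = item_corr_within,
    stress_rate_weekly = stress_rate_weekly,
    stress_effect = stress_effect,
    sleep = sleep,
    steps_daily_mean = steps_daily_mean,
    seed = as.integer(seed))
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

validate_cohort_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid cohort config: field '%s' %s", field, why),
         call. = FALSE)
  }
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || any(v < 0 | v > 1)) fail(field, "must be in [0, 1]")
  }
  chk_vec8 <- function(field, lo, hi) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 8) fail(field, "must be a numeric 8-vector")
    if (any(v < lo | v > hi)) fail(field, sprintf("must be in [%s, %s]", lo, hi))
  }
  if (!is.numeric(cfg$n_mdd) || cfg$n_mdd < 1) fail("n_mdd", "must be >= 1")
  if (!is.numeric(cfg$n_control) || cfg$n_control < 1)
    fail("n_control", "must be >= 1")
  if (!is.numeric(cfg$n_days) || cfg$n_days < 2) fail("n_days", "must be >= 2")
  if (cfg$prompts_per_day != 2) fail("prompts_per_day", "must be 2 (AM + PM)")
  chk_prob("miss_prob")
  chk_prob("zero_inflation_ctrl")
  chk_vec8("item_means_mdd", 0, 100)
  chk_vec8("item_means_ctrl", 0, 100)
  chk_vec8("item_sd_within", 0, Inf)
  chk_vec8("between_person_sd", 0, Inf)
  if (!is.numeric(cfg$ar1_rho) || cfg$ar1_rho < 0 || cfg$ar1_rho >= 1)
    fail("ar1_rho", "must be in [0, 1)")
  chk_prob("item_corr_between")
  chk_prob("item_corr_within")
  am <- hm_to_min(cfg$am_window); pm <- hm_to_min(cfg$pm_window)
  if (length(am) != 2 || am[1] >= am[2]) fail("am_window", "must be an ordered pair")
  if (length(pm) != 2 || pm[1] >= pm[2]) fail("pm_window", "must be an ordered pair")
  if (am[2] > pm[1]) fail("pm_window", "must not overlap am_window")
  if (any(cfg$stress_rate_weekly < 0)) fail("stress_rate_weekly", "must be >= 0")
  if (!all(c("MDD", "control") %in% names(cfg$stress_rate_weekly)))
    fail("stress_rate_weekly", "must be named with MDD and control entries")
  if (!all(c("MDD", "control") %in% names(cfg$steps_daily_mean)))
    fail("steps_daily_mean", "must be named with MDD and control entries")
  for (g in c("MDD", "control")) {
    s <- cfg$sleep[[g]]
    if (is.null(s)) fail("sleep", sprintf("is missing group '%s'", g))
    if (s$tst_mean_min <= 180) fail("sleep", "tst_mean_min must exceed the 180-min nap bound")
    r <- s$nap_dur_range_min
    if (length(r) != 2 || r[1] >= r[2] || r[2] >= 180)
      fail("sleep", "nap_dur_range_min must be an ordered pair below 180")
  }
  if (any(cfg$steps_daily_mean < 0)) fail("steps_daily_mean", "must be >= 0")
  if (is.na(cfg$seed)) fail("seed", "must be an integer")
  invisible(cfg)
}

#' Read / write a cohort configuration as YAML
#'
#' @param path YAML file with any subset of [cohort_config()] fields;
#'   unlisted fields keep their defaults.
#' @param seed Optional override of the file's seed (the CLI `--seed` flag).
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path, seed = NULL) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0)
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in c("stress_rate_weekly", "steps_daily_mean")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(seed)) raw$seed <- as.integer(seed)
  do.call(cohort_config, raw)
}

#' @rdname read_cohort_config
#' @param config A `cohort_config`.
#' @export
write_cohort_config <- function(config, path) {
  x <- unclass(config)
  # named atomic vectors must become maps, not bare sequences
  for (nm in c("stress_rate_weekly", "steps_daily_mean"))
    x[[nm]] <- as.list(x[[nm]])
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d MDD + %d control participants, %d days x %d prompts\n",
    x$n_mdd, x$n_control, x$n_days, x$prompts_per_day))
  cat(sprintf("  windows AM %s-%s, PM %s-%s; miss_prob %.3f; seed %d\n",
              x$am_window[1], x$am_window[2], x$pm_window[1], x$pm_window[2],
              x$miss_prob, x$seed))
  invisible(x)
}
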