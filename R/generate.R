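# Synthetic cohort generator: EMA streams, weekly stress checklists,
# Fitbit-style sleep logs and minute-level steps with serialized ground truth.

.study_start <- as.Date("2024-01-08")  # fixed anchor Monday; day_index 0

# Mean of a normal clipped (not truncated) to [lo, hi].
clip_mean <- function(mu, sd, lo = 0, hi = 100) {
  a <- (lo - mu) / sd
  b <- (hi - mu) / sd
  mu * (stats::pnorm(b) - stats::pnorm(a)) -
    sd * (stats::dnorm(b) - stats::dnorm(a)) +
    lo * stats::pnorm(a) + hi * (1 - stats::pnorm(b))
}

# Latent mean whose clipped (and optionally zero-inflated) marginal over the
# generator's discrete states (AM/PM diurnal contrast x stress week) hits the
# configured target mean.
latent_mean_for_target <- function(target, sd, deltas, probs, zi = 0) {
  f <- function(m) (1 - zi) * sum(probs * clip_mean(m + deltas, sd)) - target
  stats::uniroot(f, c(-500, 600), tol = 1e-9)$root
}

# Stationary AR(1) series with unit marginal variance.
ar1_series <- function(n, rho) {
  e <- stats::rnorm(n)
  if (rho == 0 || n == 1) return(e)
  x <- numeric(n)
  x[1] <- e[1]
  s <- sqrt(1 - rho^2)
  for (t in 2:n) x[t] <- rho * x[t - 1] + s * e[t]
  x
}

# Diurnal/stress state grid used both for calibration and generation.
state_grid <- function(group, cfg) {
  d <- if (group == "MDD") cfg$diurnal_effect_mdd else 0
  rate <- cfg$stress_rate_weekly[[group]]
  p_s <- 1 - exp(-rate)
  e <- cfg$stress_effect
  time_delta <- c(AM = d / 2, PM = -d / 2)
  stress_delta <- c(yes = e * (1 - p_s), no = -e * p_s)
  stress_prob <- c(yes = p_s, no = 1 - p_s)
  deltas <- outer(time_delta, stress_delta, "+")
  probs <- outer(c(0.5, 0.5), stress_prob)
  list(deltas = as.vector(deltas), probs = as.vector(probs),
       time_delta = time_delta, stress_delta = stress_delta, p_s = p_s)
}

# Calibrated latent item means per group (deterministic; no RNG).
latent_means <- function(cfg) {
  sd_tot <- sqrt(cfg$item_sd_within^2 + cfg$between_person_sd^2)
  out <- list()
  for (g in c("MDD", "control")) {
    st <- state_grid(g, cfg)
    target <- if (g == "MDD") cfg$item_means_mdd else cfg$item_means_ctrl
    zi <- if (g == "control") cfg$zero_inflation_ctrl else 0
    out[[g]] <- vapply(seq_len(8), function(j) {
      latent_mean_for_target(target[j], sd_tot[j], st$deltas, st$probs, zi)
    }, numeric(1))
  }
  out
}

gen_roster_row <- function(pid, group) {
  if (group == "MDD") {
    age <- round(min(26, max(14, stats::rnorm(1, 17.91, 2.98))))
    sex <- if (stats::runif(1) < 0.65) "F" else "M"
    phq9 <- round(min(27, max(0, stats::rnorm(1, 9.05, 5.81))))
    gad7 <- round(min(21, max(0, stats::rnorm(1, 6.65, 6.34))))
  } else {
    age <- round(min(27, max(14, stats::rnorm(1, 22.31, 3.90))))
    sex <- if (stats::runif(1) < 0.92) "F" else "M"
    phq9 <- round(min(27, max(0, stats::rnorm(1, 1.69, 1.32))))
    gad7 <- round(min(21, max(0, stats::rnorm(1, 2.31, 2.72))))
  }
  tibble::tibble(participant_id = pid, group = group, age = age, sex = sex,
                 phq9 = phq9, gad7 = gad7)
}

gen_participant_ema <- function(pid, group, cfg, mu_lat) {
  n_days <- cfg$n_days
  n_slots <- n_days * 2L
  day <- rep(seq_len(n_days) - 1L, each = 2L)
  window <- rep(c("AM", "PM"), n_days)
  week <- day %/% 7L + 1L
  n_weeks <- max(week)
  am <- hm_to_min(cfg$am_window); pm <- hm_to_min(cfg$pm_window)

  st <- state_grid(group, cfg)

  # 1. prompt response times, uniform within the window, minute resolution
  u <- stats::runif(n_slots)
  minute <- ifelse(window == "AM",
                   am[1] + floor(u * (am[2] - am[1])),
                   pm[1] + floor(u * (pm[2] - pm[1])))
  ts <- as.POSIXct(.study_start, tz = "UTC") + day * 86400 + minute * 60

  # 2. person-level intercepts: one-factor structure across items
  g_fac <- stats::rnorm(1)
  u8 <- stats::rnorm(8)
  lam <- cfg$item_corr_between
  intercept <- cfg$between_person_sd * (lam * g_fac + sqrt(1 - lam^2) * u8)

  # 3. within-person noise: shared check-in AR(1) + item-specific AR(1)
  c_t <- ar1_series(n_slots, cfg$ar1_rho)
  z <- matrix(0, nrow = 8, ncol = n_slots)
  for (j in 1:8) z[j, ] <- ar1_series(n_slots, cfg$ar1_rho)
  th <- cfg$item_corr_within
  noise <- cfg$item_sd_within *
    (sqrt(th) * matrix(c_t, 8, n_slots, byrow = TRUE) + sqrt(1 - th) * z)

  # 4. weekly stress process
  rate <- cfg$stress_rate_weekly[[group]]
  n_events <- pmin(12L, stats::rpois(n_weeks, rate))
  events <- lapply(n_events, function(n) {
    if (n == 0) character(0) else sample(.stress_events, n)
  })
  stress_week <- n_events >= 1
  stress_delta_wk <- ifelse(stress_week, st$stress_delta["yes"],
                            st$stress_delta["no"])

  # 5. latent scores -> clipped slider scores
  time_delta <- st$time_delta[window]
  latent <- matrix(mu_lat, 8, n_slots) + intercept +
    matrix(time_delta + stress_delta_wk[week], 8, n_slots, byrow = TRUE) +
    noise
  scores <- matrix(round(pmin(100, pmax(0, latent))), nrow = 8)

  # 6. control zero-inflation (per item response)
  if (group == "control" && cfg$zero_inflation_ctrl > 0) {
    zmask <- matrix(stats::runif(8 * n_slots) < cfg$zero_inflation_ctrl,
                    8, n_slots)
    scores[zmask] <- 0
  }

  # 7. missingness, MCAR after score generation
  miss <- stats::runif(n_slots) < cfg$miss_prob

  # weekly stress checklist rides on the last observed PM check-in of the week
  stress_slot <- rep(NA_integer_, n_weeks)
  for (w in seq_len(n_weeks)) {
    cand <- which(week == w & window == "PM" & !miss)
    if (length(cand) > 0) stress_slot[w] <- max(cand)
  }
  is_stress_prompt <- seq_len(n_slots) %in% stress_slot
  stress_events_str <- character(n_slots)
  for (w in seq_len(n_weeks)) {
    if (!is.na(stress_slot[w]))
      stress_events_str[stress_slot[w]] <- paste(events[[w]], collapse = ";")
  }

  obs <- which(!miss)
  checkins <- tibble::tibble(
    participant_id = pid,
    timestamp = ts[obs],
    item_1 = scores[1, obs], item_2 = scores[2, obs], item_3 = scores[3, obs],
    item_4 = scores[4, obs], item_5 = scores[5, obs], item_6 = scores[6, obs],
    item_7 = scores[7, obs], item_8 = scores[8, obs],
    is_stress_prompt = is_stress_prompt[obs],
    stress_events = stress_events_str[obs])

  stress <- tibble::tibble(
    participant_id = pid,
    week_index = which(!is.na(stress_slot)),
    events = vapply(which(!is.na(stress_slot)),
                    function(w) paste(events[[w]], collapse = ";"), ""),
    n_events = n_events[!is.na(stress_slot)])

  truth <- list(
    intercepts = tibble::tibble(participant_id = pid, item = .ema_items,
                                intercept = intercept),
    severity_factor = g_fac,
    stress_weeks = tibble::tibble(participant_id = pid,
                                  week_index = seq_len(n_weeks),
                                  n_events_true = n_events,
                                  stress_week = stress_week),
    miss_mask = tibble::tibble(participant_id = pid, slot = seq_len(n_slots),
                               day_index = day, window = window,
                               missing = miss),
    latent = list(scores_all = scores, ts_all = ts, window = window, day = day))

  list(checkins = checkins, stress = stress, truth = truth)
}

overlaps_any <- function(start, end, starts, ends) {
  if (length(starts) == 0) return(FALSE)
  any(start < ends & end > starts)
}

build_stages <- function(onset, tst, tab) {
  props <- c(0.17, 0.58, 0.20) + stats::rnorm(3, 0, 0.02)
  props <- pmax(props, 0.05)
  props <- props / sum(props)
  mins <- floor(props * tst)
  mins[2] <- mins[2] + (tst - sum(mins))  # remainder to light
  names(mins) <- c("deep", "light", "rem")

  split_block <- function(total, k) {
    if (total <= 0) return(integer(0))
    k <- min(k, total)
    w <- stats::rexp(k)
    d <- floor(total * w / sum(w))
    d[1] <- d[1] + (total - sum(d))
    d[d > 0]
  }
  wake_k <- 1L + min(3L, stats::rpois(1, 1.2))
  wake_d <- split_block(tab, wake_k)
  ld <- split_block(mins["light"], 3)
  dd <- split_block(mins["deep"], 2)
  rd <- split_block(mins["rem"], 2)
  blocks <- data.frame(
    stage = c(rep("light", length(ld)), rep("deep", length(dd)),
              rep("rem", length(rd))),
    dur = c(ld, dd, rd))
  # reshuffle non-wake blocks, then insert wake bouts between them
  blocks <- blocks[sample(nrow(blocks)), ]
  if (length(wake_d) > 0) {
    pos <- sort(sample(0:nrow(blocks), length(wake_d), replace = TRUE))
    out <- blocks[0, ]
    prev <- 0
    for (i in seq_along(pos)) {
      if (pos[i] > prev) out <- rbind(out, blocks[(prev + 1):pos[i], ])
      out <- rbind(out, data.frame(stage = "wake", dur = wake_d[i]))
      prev <- pos[i]
    }
    if (prev < nrow(blocks)) out <- rbind(out, blocks[(prev + 1):nrow(blocks), ])
    blocks <- out
  }
  start <- onset + c(0, cumsum(blocks$dur[-nrow(blocks)])) * 60
  tibble::tibble(stage = blocks$stage, start = start,
                 duration_min = as.numeric(blocks$dur))
}

gen_participant_sleep <- function(pid, group, cfg) {
  sp <- cfg$sleep[[group]]
  n_days <- cfg$n_days
  eps <- list()
  starts <- numeric(0); ends <- numeric(0)
  prev_offset <- -Inf

  for (d in seq_len(n_days) - 1L) {
    noon <- as.numeric(as.POSIXct(.study_start, tz = "UTC")) +
      d * 86400 + 12 * 3600
    on_min <- stats::rnorm(1, sp$onset_mean_noon_min, sp$onset_sd_noon_min)
    lim <- 2.5 * sp$onset_sd_noon_min
    on_min <- round(min(sp$onset_mean_noon_min + lim,
                        max(sp$onset_mean_noon_min - lim, on_min)))
    onset <- noon + on_min * 60
    if (onset < prev_offset + 30 * 60) onset <- prev_offset + 30 * 60
    tst <- round(min(840, max(180, stats::rnorm(1, sp$tst_mean_min, sp$tst_sd_min))))
    tab <- round(stats::rgamma(1, shape = 6, rate = 6 / (0.13 * tst)))
    tab <- min(120, max(5, tab))
    tib <- tst + tab
    offset <- onset + tib * 60
    stages <- build_stages(as.POSIXct(onset, tz = "UTC", origin = "1970-01-01"),
                           tst, tab)
    eps[[length(eps) + 1]] <- list(onset = onset, offset = offset, tib = tib,
                                   tst = tst, tab = tab, kind = "main_sleep",
                                   stages = stages)
    starts <- c(starts, onset); ends <- c(ends, offset)
    prev_offset <- offset
  }

  # afternoon naps; rate is group-specific and higher in cases
  for (d in seq_len(n_days) - 1L) {
    noon <- as.numeric(as.POSIXct(.study_start, tz = "UTC")) +
      d * 86400 + 12 * 3600
    k <- min(2L, stats::rpois(1, sp$nap_rate_per_day))
    if (k == 0) next
    for (i in seq_len(k)) {
      tib <- round(stats::runif(1, sp$nap_dur_range_min[1],
                                sp$nap_dur_range_min[2]))
      on_min <- round(min(479, max(0, stats::rnorm(1, 180, 80))))
      placed <- FALSE
      for (shift in c(0, 90, 180)) {
        onset <- noon + (on_min + shift) * 60
        offset <- onset + tib * 60
        if (!overlaps_any(onset, offset, starts, ends)) {
          placed <- TRUE
          break
        }
      }
      if (!placed) next
      eps[[length(eps) + 1]] <- list(onset = onset, offset = offset, tib = tib,
                                     tst = tib, tab = 0, kind = "nap",
                                     stages = NULL)
      starts <- c(starts, onset); ends <- c(ends, offset)
    }
  }

  ord <- order(vapply(eps, `[[`, numeric(1), "onset"))
  eps <- eps[ord]
  tibble::tibble(
    participant_id = pid,
    episode_id = sprintf("%s_s%02d", pid, seq_along(eps)),
    onset = as.POSIXct(vapply(eps, `[[`, numeric(1), "onset"),
                       tz = "UTC", origin = "1970-01-01"),
    offset = as.POSIXct(vapply(eps, `[[`, numeric(1), "offset"),
                        tz = "UTC", origin = "1970-01-01"),
    tib_min = vapply(eps, `[[`, numeric(1), "tib"),
    tst_min = vapply(eps, `[[`, numeric(1), "tst"),
    tab_min = vapply(eps, `[[`, numeric(1), "tab"),
    kind = vapply(eps, `[[`, character(1), "kind"),
    stages = lapply(eps, function(e) {
      if (is.null(e$stages))
        tibble::tibble(stage = character(0), start = as.POSIXct(character(0), tz = "UTC"),
                       duration_min = numeric(0))
      else e$stages
    }))
}

gen_participant_steps <- function(pid, group, cfg, episodes) {
  n_min <- cfg$n_days * 1440L
  t0 <- as.numeric(as.POSIXct(.study_start, tz = "UTC"))
  ts_num <- t0 + (seq_len(n_min) - 1L) * 60
  day <- (seq_len(n_min) - 1L) %/% 1440L

  sleep_mask <- rep(FALSE, n_min)
  if (!is.null(episodes) && nrow(episodes) > 0) {
    on <- as.numeric(episodes$onset); off <- as.numeric(episodes$offset)
    for (i in seq_along(on)) {
      lo <- max(1L, as.integer(ceiling((on[i] - t0) / 60)) + 1L)
      hi <- min(n_min, as.integer(floor((off[i] - t0) / 60)))
      if (lo <= hi) sleep_mask[lo:hi] <- TRUE
    }
  }

  mult <- exp(stats::rnorm(1, 0, 0.35) - 0.35^2 / 2)
  target <- cfg$steps_daily_mean[[group]] * mult
  n_wake <- tapply(!sleep_mask, day, sum)
  lambda_day <- target / (0.3 * pmax(1, n_wake))

  active <- stats::runif(n_min) < 0.3 & !sleep_mask
  steps <- integer(n_min)
  steps[active] <- stats::rpois(sum(active), lambda_day[day[active] + 1L])
  # a few non-zero minutes deliberately planted inside sleep, to exercise
  # downstream recoding of in-bed movement
  plant <- sleep_mask & stats::runif(n_min) < 0.004
  steps[plant] <- 1L + stats::rpois(sum(plant), 8)

  list(
    steps = tibble::tibble(
      participant_id = pid,
      minute_timestamp = as.POSIXct(ts_num, tz = "UTC", origin = "1970-01-01"),
      steps = steps),
    target = target,
    n_planted = sum(plant))
}

#' Generate a full synthetic study dataset
#'
#' Simulates the complete cohort: roster (group, age, sex, baseline PHQ-9 and
#' GAD-7), twice-daily EMA check-in streams with AR(1) within-person dynamics,
#' case-only diurnal variation, weekly stress effects, control zero-inflation
#' and MCAR missingness; weekly stress checklists; per-night sleep episodes
#' with stage segments and afternoon naps; and minute-level step streams with
#' a small number of step-minutes planted inside sleep. The realized latent
#' parameters are serialized in `$truth` so recovery tests can use them as an
#' oracle. Identical config and seed give identical output; each participant
#' owns an RNG stream derived from `(seed, participant_id)`, so adding
#' participants does not perturb existing streams.
#'
#' @param config A [cohort_config()].
#' @param components Character subset of `c("ema", "sleep", "steps")`;
#'   `"steps"` requires `"sleep"` (step minutes are planted relative to sleep).
#' @return A list of class `ema_cohort` with elements `roster`, `checkins`,
#'   `stress`, `sleep`, `steps`, `truth` and `config`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            components = c("ema", "sleep", "steps")) {
  validate_cohort_config(config)
  components <- match.arg(components, c("ema", "sleep", "steps"),
                          several.ok = TRUE)
  if ("steps" %in% components && !"sleep" %in% components)
    stop("components: 'steps' requires 'sleep'", call. = FALSE)

  ids <- sprintf("3%04d", seq_len(config$n_mdd + config$n_control))
  groups <- c(rep("MDD", config$n_mdd), rep("control", config$n_control))
  mu_lat <- latent_means(config)

  roster <- list(); checkins <- list(); stress <- list()
  sleep <- list(); steps <- list()
  truth_int <- list(); truth_sw <- list(); truth_mm <- list()
  truth_part <- list()

  for (i in seq_along(ids)) {
    pid <- ids[i]; grp <- groups[i]

    set.seed(derive_seed(config$seed, paste0(pid, "/roster")))
    roster[[i]] <- gen_roster_row(pid, grp)

    target_i <- NA_real_; planted_i <- NA_integer_; sev <- NA_real_
    if ("ema" %in% components) {
      set.seed(derive_seed(config$seed, paste0(pid, "/ema")))
      ge <- gen_participant_ema(pid, grp, config, mu_lat[[grp]])
      checkins[[i]] <- ge$checkins
      stress[[i]] <- ge$stress
      truth_int[[i]] <- ge$truth$intercepts
      truth_sw[[i]] <- ge$truth$stress_weeks
      truth_mm[[i]] <- ge$truth$miss_mask
      sev <- ge$truth$severity_factor
    }
    eps <- NULL
    if ("sleep" %in% components) {
      set.seed(derive_seed(config$seed, paste0(pid, "/sleep")))
      eps <- gen_participant_sleep(pid, grp, config)
      sleep[[i]] <- eps
    }
    if ("steps" %in% components) {
      set.seed(derive_seed(config$seed, paste0(pid, "/steps")))
      gs <- gen_participant_steps(pid, grp, config, eps)
      steps[[i]] <- gs$steps
      target_i <- gs$target
      planted_i <- gs$n_planted
    }
    truth_part[[i]] <- tibble::tibble(
      participant_id = pid, group = grp, severity_factor = sev,
      steps_daily_target = target_i, steps_planted_in_sleep = planted_i)
  }

  bind0 <- function(x) if (length(x) == 0) NULL else dplyr::bind_rows(x)
  sleep_tbl <- bind0(sleep)
  out <- list(
    config = config,
    roster = dplyr::bind_rows(roster),
    checkins = bind0(checkins),
    stress = bind0(stress),
    sleep = sleep_tbl,
    steps = bind0(steps),
    truth = list(
      participants = dplyr::bind_rows(truth_part),
      item_intercepts = bind0(truth_int),
      stress_weeks = bind0(truth_sw),
      miss_mask = bind0(truth_mm),
      latent_item_means = mu_lat,
      episodes = if (is.null(sleep_tbl)) NULL else
        sleep_tbl[, c("participant_id", "episode_id", "kind",
                      "tib_min", "tst_min")]))
  class(out) <- "ema_cohort"
  out
}

#' @export
print.ema_cohort <- function(x, ...) {
  cat(sprintf("<ema_cohort> %d participants (%d MDD, %d control), seed %d\n",
              nrow(x$roster), sum(x$roster$group == "MDD"),
              sum(x$roster$group == "control"), x$config$seed))
  cat(sprintf("  check-ins: %s | stress checklists: %s | sleep episodes: %s | step minutes: %s\n",
              if (is.null(x$checkins)) "-" else nrow(x$checkins),
              if (is.null(x$stress)) "-" else nrow(x$stress),
              if (is.null(x$sleep)) "-" else nrow(x$sleep),
              if (is.null(x$steps)) "-" else nrow(x$steps)))
  invisible(x)
}
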