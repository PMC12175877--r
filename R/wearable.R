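# Wearable ingest and feature extraction: Fitbit-API-like sleep logs and
# minute-level steps; nap classification, sleep architecture/quality/
# stability features, sleep-masked daily step totals.

.sleep_stages <- c("deep", "light", "rem", "wake")

#' Classify a sleep episode as nap or main sleep
#'
#' A nap is time in bed strictly under 180 minutes; exactly 180 minutes is a
#' main sleep.
#'
#' @param tib_min Time in bed, minutes.
#' @return `"nap"` or `"main_sleep"` (vectorized).
#' @export
classify_episode <- function(tib_min) {
  ifelse(tib_min < 180, "nap", "main_sleep")
}

#' Parse a sleep-log JSON file
#'
#' Reads one participant's sleep JSON (array of episodes with `start`, `end`
#' and stage `levels`), computes time in bed (TIB), total sleep time (TST;
#' sum of non-wake stage minutes, or the full in-bed time for stage-free
#' naps), time awake in bed (TAB = TIB - TST), and classifies each episode by
#' the strict sub-180-minute nap rule. Episodes for a participant must not
#' overlap and must have offset after onset.
#'
#' @param path `sleep/<id>.json` path.
#' @param participant_id Participant the file belongs to (files are
#'   per-participant; defaults to the file's base name).
#' @return Episode tibble with a `stages` list-column.
#' @export
parse_sleep_log <- function(path, participant_id = NULL) {
  if (is.null(participant_id))
    participant_id <- sub("\\.json$", "", basename(path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (length(raw) == 0) {
    return(tibble::tibble(participant_id = character(0),
                          episode_id = character(0),
                          onset = as.POSIXct(character(0), tz = "UTC"),
                          offset = as.POSIXct(character(0), tz = "UTC"),
                          tib_min = numeric(0), tst_min = numeric(0),
                          tab_min = numeric(0), kind = character(0),
                          stages = list()))
  }
  eps <- lapply(seq_along(raw), function(i) {
    e <- raw[[i]]
    onset <- parse_ts(e$start)
    offset <- parse_ts(e$end)
    if (is.na(onset) || is.na(offset))
      stop("unparseable episode timestamps in ", path, call. = FALSE)
    if (offset <= onset)
      stop(sprintf("sleep episode with offset <= onset in %s: %s -> %s",
                   path, fmt_ts(onset), fmt_ts(offset)), call. = FALSE)
    tib <- as.numeric(difftime(offset, onset, units = "mins"))
    lv <- e$levels
    if (length(lv) > 0) {
      stg <- vapply(lv, function(l) as.character(l$stage), "")
      bad <- setdiff(stg, .sleep_stages)
      if (length(bad) > 0)
        stop(sprintf("malformed stage name(s) in %s: %s", path,
                     paste(unique(bad), collapse = ", ")), call. = FALSE)
      dur <- vapply(lv, function(l) as.numeric(l$duration_sec) / 60, 1)
      st_start <- parse_ts(vapply(lv, function(l) as.character(l$start), ""))
      if (sum(dur) > tib + 1e-6)
        stop("stage durations exceed time in bed in ", path, call. = FALSE)
      stages <- tibble::tibble(stage = stg, start = st_start,
                               duration_min = dur)
    } else {
      stages <- tibble::tibble(stage = character(0),
                               start = as.POSIXct(character(0), tz = "UTC"),
                               duration_min = numeric(0))
    }
    kind <- classify_episode(tib)
    if (kind == "nap" && nrow(stages) > 0) {
      warning("stage detail on a sub-180-minute episode in ", path,
              "; treated as a stage-free nap", call. = FALSE)
      stages <- stages[0, ]
    }
    tst <- if (nrow(stages) > 0) {
      sum(stages$duration_min[stages$stage != "wake"])
    } else tib
    list(onset = onset, offset = offset, tib = tib, tst = tst,
         tab = tib - tst, kind = kind, stages = stages)
  })
  ord <- order(vapply(eps, function(e) as.numeric(e$onset), 1))
  eps <- eps[ord]
  ons <- vapply(eps, function(e) as.numeric(e$onset), 1)
  offs <- vapply(eps, function(e) as.numeric(e$offset), 1)
  if (length(eps) > 1) {
    ov <- which(ons[-1] < offs[-length(offs)])
    if (length(ov) > 0) {
      i <- ov[1]
      stop(sprintf("overlapping sleep episodes for %s: [%s, %s) and [%s, %s)",
                   participant_id,
                   fmt_ts(eps[[i]]$onset), fmt_ts(eps[[i]]$offset),
                   fmt_ts(eps[[i + 1]]$onset), fmt_ts(eps[[i + 1]]$offset)),
           call. = FALSE)
    }
  }
  tibble::tibble(
    participant_id = participant_id,
    episode_id = sprintf("%s_s%02d", participant_id, seq_along(eps)),
    onset = as.POSIXct(ons, tz = "UTC", origin = "1970-01-01"),
    offset = as.POSIXct(offs, tz = "UTC", origin = "1970-01-01"),
    tib_min = vapply(eps, function(e) e$tib, 1),
    tst_min = vapply(eps, function(e) e$tst, 1),
    tab_min = vapply(eps, function(e) e$tab, 1),
    kind = vapply(eps, function(e) e$kind, ""),
    stages = lapply(eps, function(e) e$stages))
}

#' Parse a minute-level step JSON file
#'
#' @param path `steps/<id>.json` (array of `{minute_timestamp, steps}`).
#' @param participant_id Defaults to the file's base name.
#' @return Tibble participant_id, minute_timestamp, steps, masked (FALSE).
#' @export
parse_steps <- function(path, participant_id = NULL) {
  if (is.null(participant_id))
    participant_id <- sub("\\.json$", "", basename(path))
  raw <- jsonlite::fromJSON(path)
  if (length(raw) == 0 || nrow(raw) == 0) {
    return(tibble::tibble(participant_id = character(0),
                          minute_timestamp = as.POSIXct(character(0), tz = "UTC"),
                          steps = integer(0), masked = logical(0)))
  }
  if (any(raw$steps < 0))
    stop("negative step counts in ", path, call. = FALSE)
  tibble::tibble(participant_id = participant_id,
                 minute_timestamp = parse_ts(raw$minute_timestamp),
                 steps = as.integer(raw$steps),
                 masked = FALSE)
}

#' Recode steps recorded during documented sleep to zero
#'
#' Any step minute whose timestamp falls in `[onset, offset)` of one of the
#' participant's sleep episodes is recoded to 0 steps and flagged `masked`
#' (in-bed movement, not ambulation). Idempotent; never increases a count.
#'
#' @param steps Step tibble ([parse_steps()] or generator output).
#' @param episodes Sleep episode tibble for the same participants.
#' @return `steps` with recoded `steps` and a `masked` flag.
#' @export
mask_sleep_steps <- function(steps, episodes) {
  if (!"masked" %in% names(steps)) steps$masked <- FALSE
  if (is.null(episodes) || nrow(episodes) == 0) return(steps)
  ts <- as.numeric(steps$minute_timestamp)
  masked <- steps$masked
  for (pid in unique(steps$participant_id)) {
    idx <- which(steps$participant_id == pid)
    ep <- episodes[episodes$participant_id == pid, ]
    if (nrow(ep) == 0) next
    for (i in seq_len(nrow(ep))) {
      hit <- ts[idx] >= as.numeric(ep$onset[i]) &
        ts[idx] < as.numeric(ep$offset[i])
      masked[idx[hit]] <- TRUE
    }
  }
  steps$masked <- masked
  steps$steps[masked] <- 0L
  steps
}

#' Daily step totals
#'
#' Calendar-day sums of (typically sleep-masked) minute-level steps.
#'
#' @param steps Step tibble.
#' @param roster Optional roster; adds the group column.
#' @return Tibble participant_id, date, steps (one row per observed day).
#' @export
daily_steps <- function(steps, roster = NULL) {
  out <- dplyr::summarise(
    dplyr::group_by(steps, participant_id,
                    date = date_of(minute_timestamp)),
    steps = sum(steps), .groups = "drop")
  if (!is.null(roster))
    out <- dplyr::left_join(out, roster[, c("participant_id", "group")],
                            by = "participant_id")
  out
}

# night attribution: an episode belongs to the night of its onset date if it
# starts after noon, else to the previous calendar date (crossed midnight)
night_date <- function(onset) {
  date_of(onset) - as.integer(clock_minutes(onset) < 720)
}

#' Per-participant sleep feature set
#'
#' Extracts the sleep architecture, quality and stability features used by
#' the downstream models. TST/TIB/TAB statistics and the coefficient of
#' variation of TST are computed over *all* logged sleeps (naps included);
#' stage minutes, stage percentages and wake-bout counts use main sleeps only
#' (naps carry no stage breakdown). Stage percentages are stage minutes over
#' total stage-classified (deep+light+rem) minutes. Efficiency is the
#' per-episode TST/TIB ratio averaged over episodes. Onset/offset modes are
#' on clock-hour bins and onset/offset SDs on the minutes-from-noon axis,
#' over all logged sleeps.
#'
#' @param episodes Sleep episode tibble (possibly several participants).
#' @param hypersomnia_min TST threshold (minutes) above which a main sleep
#'   counts as a hypersomnia night; the cutoff is a configurable convention.
#' @return One row per participant; participants with no main sleep are
#'   flagged `has_main_sleep = FALSE` with stage features `NA`. Attribute
#'   `metadata` records the conventions.
#' @export
sleep_features <- function(episodes, hypersomnia_min = 600) {
  stopifnot(nrow(episodes) > 0)
  rows <- lapply(split(episodes, episodes$participant_id), function(ep) {
    main <- ep[ep$kind == "main_sleep", ]
    naps <- ep[ep$kind == "nap", ]
    has_main <- nrow(main) > 0
    if (!has_main)
      warning("participant ", ep$participant_id[1],
              " has no main sleep; feature set flagged empty", call. = FALSE)

    stage_tot <- c(deep = NA_real_, light = NA_real_, rem = NA_real_)
    stage_mean <- stage_tot; stage_sd <- stage_tot; stage_pct <- stage_tot
    n_wake_bouts <- NA_integer_
    if (has_main) {
      per_night <- lapply(main$stages, function(st) {
        v <- c(deep = 0, light = 0, rem = 0)
        if (nrow(st) > 0) {
          agg <- tapply(st$duration_min, st$stage, sum)
          for (s in c("deep", "light", "rem"))
            if (s %in% names(agg)) v[s] <- agg[[s]]
        }
        v
      })
      m <- do.call(rbind, per_night)
      stage_mean <- colMeans(m)
      stage_sd <- apply(m, 2, stats::sd)
      stage_tot <- colSums(m)
      denom <- sum(stage_tot)
      stage_pct <- if (denom > 0) 100 * stage_tot / denom else stage_tot * NA
      n_wake_bouts <- sum(vapply(main$stages, function(st) {
        sum(st$stage == "wake" & st$duration_min >= 5)
      }, 1L))
    }

    all_tst <- ep$tst_min
    onset_noon <- minutes_from_noon(ep$onset)
    offset_noon <- minutes_from_noon(ep$offset)
    mode_hour <- function(ts) {
      h <- as.integer(format(ts, "%H", tz = "UTC"))
      tab <- table(h)
      as.integer(names(tab)[which.max(tab)])  # ties -> smallest hour
    }
    tibble::tibble(
      participant_id = ep$participant_id[1],
      has_main_sleep = has_main,
      n_nights = nrow(ep),
      n_main_sleeps = nrow(main),
      n_naps = nrow(naps),
      tst_mean = mean(all_tst), tst_sd = stats::sd(all_tst),
      tib_mean = mean(ep$tib_min), tib_sd = stats::sd(ep$tib_min),
      tab_mean = mean(ep$tab_min), tab_sd = stats::sd(ep$tab_min),
      deep_mean = stage_mean[["deep"]], deep_sd = stage_sd[["deep"]],
      deep_pct = stage_pct[["deep"]],
      light_mean = stage_mean[["light"]], light_sd = stage_sd[["light"]],
      light_pct = stage_pct[["light"]],
      rem_mean = stage_mean[["rem"]], rem_sd = stage_sd[["rem"]],
      rem_pct = stage_pct[["rem"]],
      efficiency = mean(ep$tst_min / ep$tib_min),
      n_wake_bouts_ge5 = n_wake_bouts,
      n_hypersomnia_nights = if (has_main)
        sum(main$tst_min > hypersomnia_min) else 0L,
      cov_tst = if (length(all_tst) >= 2 && mean(all_tst) > 0)
        100 * stats::sd(all_tst) / mean(all_tst) else NA_real_,
      mode_onset_hour = mode_hour(ep$onset),
      mode_offset_hour = mode_hour(ep$offset),
      sd_onset_noon_min = stats::sd(onset_noon),
      sd_offset_noon_min = stats::sd(offset_noon))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "metadata") <- list(
    hypersomnia_min = hypersomnia_min,
    nap_rule = "time in bed < 180 min (strict)",
    stage_pct_denominator = "deep+light+rem minutes, main sleeps only",
    tst_tib_scope = "all logged sleeps (naps included)",
    onset_axis = "minutes from 12:00")
  out
}

#' Group-level sleep summary (report schema)
#'
#' Pools episodes within group for the descriptive sleep report: nights and
#' individuals, TST/TIB/TAB mean (SD), stage minutes and percentages,
#' efficiency, counts of >= 5-minute wake bouts, hypersomnia nights and naps,
#' pooled CoV of TST, and onset/offset mode hours and minutes-from-noon SDs.
#'
#' @param episodes Sleep episode tibble.
#' @param roster Roster with the group column.
#' @param hypersomnia_min See [sleep_features()].
#' @return Tibble with one column of metrics and one column per group.
#' @export
sleep_group_summary <- function(episodes, roster, hypersomnia_min = 600) {
  ep <- dplyr::left_join(episodes, roster[, c("participant_id", "group")],
                         by = "participant_id")
  cols <- lapply(split(ep, ep$group), function(d) {
    main <- d[d$kind == "main_sleep", ]
    stage_min <- lapply(c("deep", "light", "rem"), function(s) {
      vapply(main$stages, function(st) {
        if (nrow(st) == 0) 0 else sum(st$duration_min[st$stage == s])
      }, 1)
    })
    names(stage_min) <- c("deep", "light", "rem")
    denom <- sum(unlist(stage_min))
    msd <- function(x) sprintf("%.2f (%.2f)", mean(x), stats::sd(x))
    mode_hour <- function(ts) {
      h <- as.integer(format(ts, "%H", tz = "UTC"))
      tab <- table(h)
      sprintf("%02d:00", as.integer(names(tab)[which.max(tab)]))
    }
    c(nights_n = as.character(nrow(d)),
      individuals_n = as.character(length(unique(d$participant_id))),
      tst_mean_sd = msd(d$tst_min),
      tib_mean_sd = msd(d$tib_min),
      tab_mean_sd = msd(d$tab_min),
      deep_mean_sd = msd(stage_min$deep),
      deep_pct = sprintf("%.0f", 100 * sum(stage_min$deep) / denom),
      light_mean_sd = msd(stage_min$light),
      light_pct = sprintf("%.0f", 100 * sum(stage_min$light) / denom),
      rem_mean_sd = msd(stage_min$rem),
      rem_pct = sprintf("%.0f", 100 * sum(stage_min$rem) / denom),
      efficiency = sprintf("%.2f", mean(d$tst_min / d$tib_min)),
      wake_bouts_ge5 = as.character(sum(vapply(main$stages, function(st) {
        sum(st$stage == "wake" & st$duration_min >= 5)
      }, 1L))),
      hypersomnia_nights = as.character(sum(main$tst_min > hypersomnia_min)),
      n_naps = as.character(sum(d$kind == "nap")),
      cov_tst = sprintf("%.2f", 100 * stats::sd(d$tst_min) / mean(d$tst_min)),
      mode_onset_hour = mode_hour(d$onset),
      sd_onset_noon_min = sprintf("%.2f", stats::sd(minutes_from_noon(d$onset))),
      mode_offset_hour = mode_hour(d$offset),
      sd_offset_noon_min = sprintf("%.2f", stats::sd(minutes_from_noon(d$offset))))
  })
  metrics <- names(cols[[1]])
  out <- tibble::tibble(metric = metrics)
  for (g in names(cols)) out[[g]] <- unname(cols[[g]])
  out
}
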