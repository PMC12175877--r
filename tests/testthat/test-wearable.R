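ep_json <- function(start, end, levels = list()) {
  list(start = start, end = end, levels = levels)
}
lv <- function(stage, start, dur_min) {
  list(stage = stage, start = start, duration_sec = dur_min * 60)
}

test_that("sleep log parsing computes tib/tst/tab and classifies episodes", {
  p <- file.path(tempdir(), "sl1.json")
  write_sleep_json(list(
    # 22:00 -> 06:30 with 30 min wake: tib 510, tst 480, tab 30
    ep_json("2024-01-08T22:00:00", "2024-01-09T06:30:00", list(
      lv("wake", "2024-01-08T22:00:00", 30),
      lv("light", "2024-01-08T22:30:00", 300),
      lv("deep", "2024-01-09T03:30:00", 80),
      lv("rem", "2024-01-09T04:50:00", 100))),
    # stage-free 60-min nap
    ep_json("2024-01-09T14:00:00", "2024-01-09T15:00:00"),
    ep_json("2024-01-09T23:00:00", "2024-01-10T06:00:00", list(
      lv("light", "2024-01-09T23:00:00", 420)))), p)
  eps <- parse_sleep_log(p, "px")
  expect_equal(nrow(eps), 3)
  first <- eps[1, ]
  expect_equal(first$tib_min, 510)
  expect_equal(first$tst_min, 480)
  expect_equal(first$tab_min, 30)
  expect_equal(first$kind, "main_sleep")
  expect_equal(eps$kind[2], "nap")
  expect_equal(eps$tst_min[2], 60)  # naps: stage-free total
  expect_equal(eps$tab_min, eps$tib_min - eps$tst_min)  # exact identity
  file.remove(p)
})

test_that("malformed, inverted and overlapping episodes are rejected", {
  p <- file.path(tempdir(), "sl2.json")
  write_sleep_json(list(
    ep_json("2024-01-08T22:00:00", "2024-01-09T06:00:00", list(
      lv("snooze", "2024-01-08T22:00:00", 480)))), p)
  expect_error(parse_sleep_log(p), "stage name")
  write_sleep_json(list(
    ep_json("2024-01-09T06:00:00", "2024-01-08T22:00:00")), p)
  expect_error(parse_sleep_log(p), "offset <= onset")
  write_sleep_json(list(
    ep_json("2024-01-08T22:00:00", "2024-01-09T06:00:00", list(
      lv("light", "2024-01-08T22:00:00", 480))),
    ep_json("2024-01-09T05:00:00", "2024-01-09T09:00:00", list(
      lv("light", "2024-01-09T05:00:00", 240)))), p)
  expect_error(parse_sleep_log(p), "overlapping.*2024-01-09T05:00:00")
  file.remove(p)
})

test_that("nap classification is strict at 180 minutes", {
  expect_equal(classify_episode(60), "nap")
  expect_equal(classify_episode(179), "nap")
  expect_equal(classify_episode(180), "main_sleep")
  expect_equal(classify_episode(420), "main_sleep")
})

test_that("minutes_from_noon anchors at 12:00 and wraps at midnight", {
  ts <- function(x) as.POSIXct(x, tz = "UTC")
  expect_equal(minutes_from_noon(ts("2024-01-08 12:00:00")), 0L)
  expect_equal(minutes_from_noon(ts("2024-01-08 23:00:00")), 660L)
  expect_equal(minutes_from_noon(ts("2024-01-09 06:00:00")), 1080L)
  expect_equal(minutes_from_noon(ts("2024-01-08 11:59:00")), 1439L)
  # SD on this axis is invariant to shifting all clock times by 24 h
  set.seed(31)
  t0 <- ts("2024-01-08 12:00:00") + round(stats::runif(50, 0, 86399))
  expect_equal(stats::sd(minutes_from_noon(t0)),
               stats::sd(minutes_from_noon(t0 + 86400)))
})

test_that("sleep features follow the nap inclusion/exclusion rules", {
  mk <- function(tib, onset, stages) {
    tst <- if (nrow(stages) > 0) sum(stages$duration_min[stages$stage != "wake"]) else tib
    tibble::tibble(participant_id = "p1", episode_id = "e",
                   onset = onset, offset = onset + tib * 60,
                   tib_min = tib, tst_min = tst, tab_min = tib - tst,
                   kind = classify_episode(tib), stages = list(stages))
  }
  st <- function(...) {
    args <- list(...)
    tibble::tibble(stage = vapply(args, `[[`, "", 1),
                   start = as.POSIXct("2024-01-08 22:00", tz = "UTC"),
                   duration_min = vapply(args, function(a) as.numeric(a[[2]]), 1))
  }
  t1 <- as.POSIXct("2024-01-08 22:00", tz = "UTC")
  eps <- dplyr::bind_rows(
    mk(400, t1, st(list("wake", 40), list("light", 200), list("deep", 80),
                   list("rem", 80))),
    mk(400, t1 + 86400, st(list("wake", 4), list("light", 216),
                           list("deep", 90), list("rem", 90))),
    mk(90, t1 + 2 * 86400 + 15 * 3600, st()[0, ]))
  fs <- sleep_features(eps)
  expect_equal(fs$n_nights, 3)       # naps count toward TST/TIB statistics
  expect_equal(fs$n_naps, 1)
  expect_equal(fs$n_main_sleeps, 2)  # stage statistics use main sleeps only
  expect_equal(fs$tst_mean, mean(c(360, 396, 90)))
  expect_equal(fs$deep_mean, 85)
  expect_equal(fs$light_mean, 208)
  # wake bouts >= 5 min: only the 40-min bout counts
  expect_equal(fs$n_wake_bouts_ge5, 1)
  # stage percentages sum to 100 over deep/light/rem
  expect_equal(fs$deep_pct + fs$light_pct + fs$rem_pct, 100)
  # efficiency averages per-episode TST/TIB (nap ratio = 1)
  expect_equal(fs$efficiency, mean(c(360 / 400, 396 / 400, 1)))

  # two-point CoV of TST oracle
  eps2 <- dplyr::bind_rows(
    mk(300, t1, st(list("light", 300))),
    mk(500, t1 + 86400, st(list("light", 500))))
  fs2 <- sleep_features(eps2)
  expect_equal(fs2$cov_tst,
               100 * stats::sd(c(300, 500)) / mean(c(300, 500)))
  # identical nightly TST: cov_tst = 0
  eps3 <- dplyr::bind_rows(mk(400, t1, st(list("light", 400))),
                           mk(400, t1 + 86400, st(list("light", 400))))
  expect_equal(sleep_features(eps3)$cov_tst, 0)
  # hypersomnia nights respect the configurable threshold
  eps4 <- dplyr::bind_rows(mk(700, t1, st(list("light", 650))),
                           mk(400, t1 + 86400, st(list("light", 380))))
  expect_equal(sleep_features(eps4)$n_hypersomnia_nights, 1)
  expect_equal(sleep_features(eps4, hypersomnia_min = 300)$n_hypersomnia_nights, 2)
  # no main sleep: flagged empty
  eps5 <- mk(90, t1 + 15 * 3600, st()[0, ])
  expect_warning(fs5 <- sleep_features(eps5), "no main sleep")
  expect_false(fs5$has_main_sleep)
  expect_true(is.na(fs5$deep_mean))
})

test_that("steps recorded during documented sleep are recoded to zero", {
  eps <- tibble::tibble(
    participant_id = "p1", episode_id = "e1",
    onset = as.POSIXct("2024-01-08 23:00", tz = "UTC"),
    offset = as.POSIXct("2024-01-09 07:00", tz = "UTC"),
    tib_min = 480, tst_min = 480, tab_min = 0, kind = "main_sleep",
    stages = list(tibble::tibble(stage = character(0),
                                 start = as.POSIXct(character(0), tz = "UTC"),
                                 duration_min = numeric(0))))
  sm <- tibble::tibble(
    participant_id = "p1",
    minute_timestamp = as.POSIXct("2024-01-08 22:58", tz = "UTC") +
      (0:5) * 60,
    steps = c(7L, 3L, 12L, 5L, 0L, 9L))
  masked <- mask_sleep_steps(sm, eps)
  # 23:00 onward (index 3+) is inside [onset, offset)
  expect_equal(masked$steps, c(7L, 3L, 0L, 0L, 0L, 0L))
  expect_equal(masked$masked, c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_true(all(masked$steps[masked$masked] == 0))
  expect_lte(sum(masked$steps), sum(sm$steps))
  # idempotent
  again <- mask_sleep_steps(masked, eps)
  expect_identical(again, masked)
  # boundary: the offset minute itself is not masked
  sm2 <- tibble::tibble(participant_id = "p1",
                        minute_timestamp = as.POSIXct("2024-01-09 07:00",
                                                      tz = "UTC"),
                        steps = 4L)
  expect_equal(mask_sleep_steps(sm2, eps)$steps, 4L)
})

test_that("daily step totals sum calendar days", {
  sm <- tibble::tibble(
    participant_id = "p1",
    minute_timestamp = as.POSIXct("2024-01-08 00:00", tz = "UTC") +
      (0:(2 * 1440 - 1)) * 60,
    steps = c(rep(1L, 1440), rep(0L, 1440)))
  ds <- daily_steps(sm)
  expect_equal(ds$steps, c(1440, 0))  # constant-1 day, then an empty day
})

test_that("feature extraction recovers generator truth on synthetic sleep", {
  co <- generate_cohort(cohort_config(seed = 17), components = "sleep")
  fs <- suppressWarnings(sleep_features(co$sleep))
  truth_naps <- tapply(co$truth$episodes$kind == "nap",
                       co$truth$episodes$participant_id, sum)
  expect_equal(fs$n_naps, as.integer(truth_naps[fs$participant_id]),
               ignore_attr = TRUE)
  # cases sleep less than controls at the configured generator scale
  grp <- co$roster$group[match(fs$participant_id, co$roster$participant_id)]
  expect_lt(mean(fs$tst_mean[grp == "MDD"]), mean(fs$tst_mean[grp == "control"]))
})
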