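test_that("invalid config fields are rejected with the field named", {
  expect_error(cohort_config(miss_prob = 1.5), "miss_prob")
  expect_error(cohort_config(n_days = 1), "n_days")
  expect_error(cohort_config(ar1_rho = 1), "ar1_rho")
  expect_error(cohort_config(item_means_mdd = rep(40, 7)), "item_means_mdd")
  expect_error(cohort_config(item_means_ctrl = c(rep(40, 7), 120)),
               "item_means_ctrl")
  expect_error(cohort_config(am_window = c("06:00", "17:00")), "window")
  expect_error(cohort_config(zero_inflation_ctrl = -0.1),
               "zero_inflation_ctrl")
})

test_that("no missingness yields the full prompt schedule, timestamped in window", {
  cfg <- small_config(miss_prob = 0)
  co <- generate_cohort(cfg, components = "ema")
  expect_equal(nrow(co$checkins), (cfg$n_mdd + cfg$n_control) * cfg$n_days * 2)
  w <- assign_window(co$checkins$timestamp, cfg)
  expect_true(all(w %in% c("AM", "PM")))
  items <- as.matrix(co$checkins[paste0("item_", 1:8)])
  expect_true(all(items >= 0 & items <= 100))
})

test_that("identical config and seed give byte-identical serialized datasets", {
  cfg <- small_config(seed = 42)
  d1 <- file.path(tempdir(), "det1")
  d2 <- file.path(tempdir(), "det2")
  write_fixture_files(generate_cohort(cfg), d1)
  write_fixture_files(generate_cohort(cfg), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 5)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("adding participants does not perturb existing streams", {
  co_a <- generate_cohort(cohort_config(n_mdd = 3, n_control = 2, seed = 5),
                          components = c("ema", "sleep"))
  co_b <- generate_cohort(cohort_config(n_mdd = 5, n_control = 2, seed = 5),
                          components = c("ema", "sleep"))
  for (pid in sprintf("3%04d", 1:3)) {
    expect_identical(co_a$checkins[co_a$checkins$participant_id == pid, ],
                     co_b$checkins[co_b$checkins$participant_id == pid, ])
    expect_identical(
      co_a$sleep[co_a$sleep$participant_id == pid,
                 c("onset", "offset", "tib_min", "tst_min", "kind")],
      co_b$sleep[co_b$sleep$participant_id == pid,
                 c("onset", "offset", "tib_min", "tst_min", "kind")])
  }
})

test_that("within-person residual lag-1 autocorrelation tracks ar1_rho", {
  # truth-centered residuals pooled over items/participants; averaged over
  # seeded replicates the empirical ACF should recover the configured rho
  rho_hat <- function(seed) {
    cfg <- quiet_config(seed = seed, rho = 0.5)
    cfg$n_mdd <- 6; cfg$n_control <- 6
    co <- generate_cohort(cfg, components = "ema")
    mu <- co$truth$latent_item_means
    int <- co$truth$item_intercepts
    num <- den <- 0
    for (pid in unique(co$checkins$participant_id)) {
      grp <- co$roster$group[co$roster$participant_id == pid]
      sc <- t(as.matrix(
        co$checkins[co$checkins$participant_id == pid, paste0("item_", 1:8)]))
      res <- sc - mu[[grp]] - int$intercept[int$participant_id == pid]
      for (j in 1:8) {
        r <- res[j, ]
        num <- num + sum(r[-1] * r[-length(r)])
        den <- den + sum(r^2)
      }
    }
    num / den
  }
  est <- vapply(1:60, rho_hat, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.05)
})

test_that("generated marginals are calibrated and missingness matches miss_prob", {
  n_seeds <- 100
  mdd_mean <- ctrl_mean <- miss_frac <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    co <- generate_cohort(cohort_config(seed = s), components = "ema")
    cs <- checkin_scores(co)
    mdd_mean[s] <- mean(cs$sum[cs$group == "MDD"])
    ctrl_mean[s] <- mean(cs$sum[cs$group == "control"])
    miss_frac[s] <- mean(co$truth$miss_mask$missing)
  }
  se <- stats::sd(mdd_mean) / sqrt(n_seeds)
  expect_lt(abs(mean(mdd_mean) - sum(cohort_config()$item_means_mdd)),
            2 * se)
  se_c <- stats::sd(ctrl_mean) / sqrt(n_seeds)
  expect_lt(abs(mean(ctrl_mean) - sum(cohort_config()$item_means_ctrl)),
            max(2 * se_c, 1))
  se_m <- stats::sd(miss_frac) / sqrt(n_seeds)
  expect_lt(abs(mean(miss_frac) - cohort_config()$miss_prob), 2 * se_m)
})

test_that("nap truth agrees with the downstream classification rule", {
  co <- generate_cohort(small_config(seed = 8), components = "sleep")
  expect_identical(classify_episode(co$sleep$tib_min), co$truth$episodes$kind)
  expect_true(all(co$sleep$tib_min[co$sleep$kind == "nap"] < 180))
  # stage-free naps, staged main sleeps
  nstage <- vapply(co$sleep$stages, nrow, 1L)
  expect_true(all(nstage[co$sleep$kind == "nap"] == 0))
  expect_true(all(nstage[co$sleep$kind == "main_sleep"] > 0))
})

test_that("fixture round trip preserves the dataset", {
  cfg <- small_config(seed = 13)
  co <- generate_cohort(cfg)
  dir <- file.path(tempdir(), "roundtrip")
  manifest <- write_fixture_files(co, dir)
  expect_true(all(c("ema", "roster", "stress", "sleep", "steps") %in%
                    manifest$kind))
  # one steps.json and one sleep.json per roster participant
  expect_equal(sum(manifest$kind == "steps"), nrow(co$roster))
  expect_equal(sum(manifest$kind == "sleep"), nrow(co$roster))

  roster <- parse_roster(file.path(dir, "roster.csv"))
  expect_equal(roster$participant_id, co$roster$participant_id)
  ck <- parse_checkins(file.path(dir, "ema.csv"), roster, cfg)
  expect_equal(nrow(ck), nrow(co$checkins))
  st <- parse_stress(file.path(dir, "stress.csv"), roster)
  expect_equal(nrow(st), nrow(co$stress))

  pid <- roster$participant_id[1]
  eps <- parse_sleep_log(file.path(dir, "sleep", paste0(pid, ".json")))
  gen <- co$sleep[co$sleep$participant_id == pid, ]
  expect_equal(nrow(eps), nrow(gen))
  expect_equal(eps$tib_min, gen$tib_min)
  expect_equal(eps$tst_min, gen$tst_min)
  expect_equal(eps$kind, gen$kind)
  sm <- parse_steps(file.path(dir, "steps", paste0(pid, ".json")))
  gsm <- co$steps[co$steps$participant_id == pid, ]
  expect_equal(nrow(sm), nrow(gsm))
  expect_equal(sum(sm$steps), sum(gsm$steps))
  unlink(dir, recursive = TRUE)
})

test_that("config YAML round trip and seed override work", {
  cfg <- small_config(seed = 2, miss_prob = 0.12)
  p <- file.path(tempdir(), "cfg.yaml")
  write_cohort_config(cfg, p)
  cfg2 <- read_cohort_config(p)
  expect_equal(cfg2$miss_prob, 0.12)
  expect_equal(cfg2$item_means_mdd, cfg$item_means_mdd)
  cfg3 <- read_cohort_config(p, seed = 99)
  expect_equal(cfg3$seed, 99L)
  file.remove(p)
})
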