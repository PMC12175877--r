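# End-to-end orchestration: simulate -> write -> ingest -> features ->
# variability -> models -> report, with a run manifest.

fmt2 <- function(x) {
  if (is.numeric(x)) round(x, 2) else x
}

write_report_csv <- function(df, path, footer = NULL) {
  df <- dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), fmt2))
  readr::write_csv(df, path)
  if (!is.null(footer)) {
    lines <- sprintf("# %s: %s", names(footer),
                     vapply(footer, function(v) paste(v, collapse = ","), ""))
    con <- file(path, open = "a")
    writeLines(lines, con)
    close(con)
  }
  invisible(path)
}

#' Render the report tables
#'
#' Writes the descriptive/variability table (group x item rows, column order
#' item, group, n, %>0, mean, SD, min, max, skewness, RMSSD, CoV, ICC), the
#' group-level sleep metric table, the compliance summary and the flattened
#' model results, all with 2-decimal formatting. Each CSV ends with a
#' commented metadata footer recording the design-decision flags in effect
#' (ICC estimator, CoV aggregation mode, hypersomnia threshold, ...).
#'
#' @param out_dir Output directory.
#' @param variability [variability_table()] output (or `NULL`).
#' @param sleep_summary [sleep_group_summary()] output (or `NULL`).
#' @param compliance [compliance_summary()] output (or `NULL`).
#' @param registry [run_registry()] output (or `NULL`).
#' @param flags Named list of design-decision flags for the footer.
#' @return Character vector of written files.
#' @export
render_tables <- function(out_dir, variability = NULL, sleep_summary = NULL,
                          compliance = NULL, registry = NULL,
                          flags = list()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  base_flags <- utils::modifyList(list(
    icc_estimator = "reml_random_intercept",
    cov_mode = "participant_mean",
    hypersomnia_min = 600,
    nap_rule = "tib<180",
    window_convention = "half-open [start,end)"), flags)
  footer <- base_flags

  if (!is.null(variability)) {
    md <- attr(variability, "metadata")
    if (!is.null(md)) footer <- utils::modifyList(footer, md)
    p <- file.path(out_dir, "variability_table.csv")
    write_report_csv(variability, p, footer)
    written <- c(written, p)
  }
  if (!is.null(sleep_summary)) {
    p <- file.path(out_dir, "sleep_metrics.csv")
    write_report_csv(sleep_summary, p, footer)
    written <- c(written, p)
  }
  if (!is.null(compliance)) {
    write_compliance_report(compliance,
                            csv_path = file.path(out_dir, "compliance.csv"),
                            json_path = file.path(out_dir, "compliance.json"))
    written <- c(written, file.path(out_dir, c("compliance.csv",
                                               "compliance.json")))
  }
  if (!is.null(registry)) {
    p <- file.path(out_dir, "model_results.csv")
    write_report_csv(registry_results(registry), p, footer)
    vc <- lapply(registry, function(r) {
      list(varcomp = r$varcomp, r2_marginal = r$r2_marginal,
           r2_conditional = r$r2_conditional, singular = r$singular,
           degenerate = r$degenerate, error = r$error)
    })
    pj <- file.path(out_dir, "model_variance_components.json")
    jsonlite::write_json(vc, pj, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
    written <- c(written, p, pj)
  }
  written
}

#' Run the full pipeline
#'
#' Simulates a cohort, writes the file fixtures, re-ingests them through the
#' parsers (an honest file round trip), computes compliance, the
#' variability table, time-series exports, sleep features and masked daily
#' steps, fits the model registry, renders the report tables and writes a
#' run manifest. Fully deterministic for a given config and seed.
#'
#' @param config A [cohort_config()].
#' @param out_dir Run directory (created).
#' @param seed Optional override of `config$seed`.
#' @param cov_mode,hypersomnia_min Analysis flags (see
#'   [variability_table()], [sleep_features()]).
#' @return Invisible list with all intermediate objects and the manifest.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir, seed = NULL,
                         cov_mode = "participant_mean",
                         hypersomnia_min = 600) {
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    validate_cohort_config(config)
  }
  data_dir <- file.path(out_dir, "data")
  report_dir <- file.path(out_dir, "report")
  dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(report_dir, recursive = TRUE, showWarnings = FALSE)

  cohort <- generate_cohort(config)
  manifest_files <- write_fixture_files(cohort, data_dir)

  roster <- parse_roster(file.path(data_dir, "roster.csv"))
  checkins <- parse_checkins(file.path(data_dir, "ema.csv"), roster, config)
  stress <- parse_stress(file.path(data_dir, "stress.csv"), roster)
  compliance <- compliance_summary(checkins, roster, config)
  vt <- variability_table(checkins, roster, cov_mode = cov_mode)
  ts_raw <- export_timeseries(checkins, roster, centered = FALSE)
  ts_centered <- export_timeseries(checkins, roster, centered = TRUE)

  sleep <- dplyr::bind_rows(lapply(
    list.files(file.path(data_dir, "sleep"), full.names = TRUE),
    parse_sleep_log))
  steps <- dplyr::bind_rows(lapply(
    list.files(file.path(data_dir, "steps"), full.names = TRUE),
    parse_steps))
  masked <- mask_sleep_steps(steps, sleep)
  dsteps <- daily_steps(masked, roster)
  feats <- suppressWarnings(sleep_features(sleep, hypersomnia_min))
  sleep_sum <- sleep_group_summary(sleep, roster, hypersomnia_min)

  model_data <- build_model_data(checkins, roster, stress, sleep, dsteps,
                                 hypersomnia_min)
  registry <- run_registry(model_data)

  readr::write_csv(ts_raw, file.path(report_dir, "timeseries_raw.csv"))
  readr::write_csv(ts_centered, file.path(report_dir, "timeseries_centered.csv"))
  readr::write_csv(feats, file.path(report_dir, "sleep_features.csv"))
  readr::write_csv(dsteps, file.path(report_dir, "daily_steps.csv"))
  files <- render_tables(report_dir, variability = vt,
                         sleep_summary = sleep_sum, compliance = compliance,
                         registry = registry,
                         flags = list(cov_mode = cov_mode,
                                      hypersomnia_min = hypersomnia_min))

  # manifest paths are relative to the run directory so identical runs in
  # different locations produce identical manifests
  rel <- function(p) {
    sub(paste0("^", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1",
                         normalizePath(out_dir, mustWork = FALSE)), "/?"),
        "", normalizePath(p, mustWork = FALSE))
  }
  manifest_files$file <- vapply(manifest_files$file, rel, "")
  cfg_yaml <- yaml::as.yaml(unclass(config))
  manifest <- list(
    package_version = as.character(utils::packageVersion("emawear")),
    seed = config$seed,
    config_hash = text_hash(cfg_yaml),
    config = unclass(config),
    flags = list(cov_mode = cov_mode, hypersomnia_min = hypersomnia_min),
    inputs = manifest_files,
    outputs = vapply(c(files, file.path(report_dir,
                                        c("timeseries_raw.csv",
                                          "timeseries_centered.csv",
                                          "sleep_features.csv",
                                          "daily_steps.csv"))), rel, "",
                     USE.NAMES = FALSE),
    stage_rows = list(
      checkins = nrow(checkins), stress = nrow(stress),
      sleep_episodes = nrow(sleep), step_minutes = nrow(steps),
      long_table = nrow(model_data$item),
      models = length(registry)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "rows", POSIXt = "ISO8601")

  invisible(list(config = config, cohort = cohort, roster = roster,
                 checkins = checkins, stress = stress,
                 compliance = compliance, variability = vt,
                 sleep = sleep, steps = masked, daily_steps = dsteps,
                 sleep_features = feats, sleep_summary = sleep_sum,
                 model_data = model_data, registry = registry,
                 manifest = manifest))
}
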