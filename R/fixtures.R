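# On-disk dialects: ema.csv, roster.csv, stress.csv, per-participant
# sleep/<id>.json and steps/<id>.json (Fitbit-API-like).

#' Write a synthetic cohort to its file dialects
#'
#' Serializes an `ema_cohort` into the formats the ingest and wearable parsers
#' consume: `ema.csv` (one row per check-in), `roster.csv`, `stress.csv`, and
#' per-participant `sleep/<id>.json` and `steps/<id>.json`. A round trip
#' through the parsers reproduces the in-memory dataset.
#'
#' @param cohort An [generate_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @return A tibble manifest (`file`, `kind`, `n_records`), invisibly usable
#'   for run bookkeeping.
#' @export
write_fixture_files <- function(cohort, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir))
      stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  if (file.access(out_dir, 2) != 0)
    stop("output directory is not writable: ", out_dir, call. = FALSE)
  manifest <- list()
  add <- function(file, kind, n) {
    manifest[[length(manifest) + 1]] <<-
      tibble::tibble(file = file, kind = kind, n_records = n)
  }

  roster_path <- file.path(out_dir, "roster.csv")
  readr::write_csv(cohort$roster, roster_path)
  add(roster_path, "roster", nrow(cohort$roster))

  if (!is.null(cohort$checkins)) {
    ema <- cohort$checkins
    ema$timestamp <- fmt_ts(ema$timestamp)
    ema_path <- file.path(out_dir, "ema.csv")
    readr::write_csv(ema, ema_path)
    add(ema_path, "ema", nrow(ema))

    stress_path <- file.path(out_dir, "stress.csv")
    readr::write_csv(cohort$stress, stress_path)
    add(stress_path, "stress", nrow(cohort$stress))
  }

  if (!is.null(cohort$sleep)) {
    dir.create(file.path(out_dir, "sleep"), showWarnings = FALSE)
    for (pid in unique(cohort$roster$participant_id)) {
      eps <- cohort$sleep[cohort$sleep$participant_id == pid, ]
      path <- file.path(out_dir, "sleep", paste0(pid, ".json"))
      episodes <- lapply(seq_len(nrow(eps)), function(i) {
        st <- eps$stages[[i]]
        list(
          start = fmt_ts(eps$onset[i]),
          end = fmt_ts(eps$offset[i]),
          levels = if (nrow(st) == 0) list() else
            lapply(seq_len(nrow(st)), function(k) {
              list(stage = st$stage[k], start = fmt_ts(st$start[k]),
                   duration_sec = st$duration_min[k] * 60)
            }))
      })
      jsonlite::write_json(episodes, path, auto_unbox = TRUE, pretty = FALSE)
      add(path, "sleep", nrow(eps))
    }
  }

  if (!is.null(cohort$steps)) {
    dir.create(file.path(out_dir, "steps"), showWarnings = FALSE)
    for (pid in unique(cohort$roster$participant_id)) {
      sm <- cohort$steps[cohort$steps$participant_id == pid, ]
      path <- file.path(out_dir, "steps", paste0(pid, ".json"))
      df <- data.frame(minute_timestamp = fmt_ts(sm$minute_timestamp),
                       steps = sm$steps)
      jsonlite::write_json(df, path, dataframe = "rows")
      add(path, "steps", nrow(sm))
    }
  }

  dplyr::bind_rows(manifest)
}

#' Read a participant roster
#'
#' @param path `roster.csv` with columns participant_id, group, age, sex,
#'   phq9, gad7.
#' @return A tibble.
#' @export
parse_roster <- function(path) {
  roster <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(participant_id = "c"))
  need <- c("participant_id", "group", "age", "sex", "phq9", "gad7")
  miss <- setdiff(need, names(roster))
  if (length(miss) > 0)
    stop("roster is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(roster$group), c("MDD", "control"))
  if (length(bad) > 0)
    stop("roster has unknown groups: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(roster$participant_id))
    stop("roster participant_id values are not unique", call. = FALSE)
  roster
}

#' Read weekly stress checklists
#'
#' @param path `stress.csv` with columns participant_id, week_index, events
#'   (semicolon-joined checklist keys), n_events.
#' @param roster Optional roster for id validation.
#' @return A tibble.
#' @export
parse_stress <- function(path, roster = NULL) {
  stress <- readr::read_csv(path, show_col_types = FALSE,
                            col_types = readr::cols(participant_id = "c",
                                                    events = "c"))
  stress$events[is.na(stress$events)] <- ""
  n_listed <- vapply(strsplit(stress$events, ";", fixed = TRUE),
                     function(x) length(x[nzchar(x)]), 1L)
  if (!all(stress$n_events == n_listed))
    stop("stress.csv: n_events disagrees with the events list", call. = FALSE)
  if (any(stress$n_events > 12))
    stop("stress.csv: more than 12 checklist events in one week", call. = FALSE)
  if (!is.null(roster)) {
    unknown <- setdiff(unique(stress$participant_id), roster$participant_id)
    if (length(unknown) > 0)
      stop("stress.csv has unknown participants: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  stress
}
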