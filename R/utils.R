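# Shared time and seeding helpers. All timestamps are local wall-clock times;
# they are stored as POSIXct in UTC purely to avoid DST arithmetic.

.ts_format <- "%Y-%m-%dT%H:%M:%S"

parse_ts <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                   "%Y-%m-%d"))
  out
}

fmt_ts <- function(x) format(x, .ts_format, tz = "UTC")

#' Minutes elapsed since the most recent noon
#'
#' Re-expresses a clock time on the minutes-from-noon axis, the convention used
#' to summarise sleep onset/offset dispersion without midnight wraparound:
#' 12:00 maps to 0, 23:00 to 660, 06:00 to 1080.
#'
#' @param ts POSIXct vector (local wall-clock time).
#' @return Integer minutes in `[0, 1439]`.
#' @export
minutes_from_noon <- function(ts) {
  ts <- parse_ts(ts)
  m <- as.integer(format(ts, "%H", tz = "UTC")) * 60L +
    as.integer(format(ts, "%M", tz = "UTC"))
  (m - 720L) %% 1440L
}

clock_minutes <- function(ts) {
  as.integer(format(ts, "%H", tz = "UTC")) * 60L +
    as.integer(format(ts, "%M", tz = "UTC"))
}

date_of <- function(ts) as.Date(ts, tz = "UTC")

# "HH:MM" -> minutes after midnight
hm_to_min <- function(x) {
  if (is.numeric(x)) return(as.integer(round(x * 60)))
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) as.integer(p[1]) * 60L + as.integer(p[2]), 1L)
}

# Deterministic 31-bit seed derived from a base seed and a string key, so each
# participant/component pair owns an independent reproducible stream.
derive_seed <- function(seed, key) {
  codes <- utf8ToInt(key)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 2654435 + h + 1) %% 2147483647)
}

# FNV-1a style hash of a string, used for config fingerprints in manifests.
text_hash <- function(x) {
  codes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (c in codes) {
    h <- bitwXor(as.integer(h %% 2147483647), c)
    h <- (as.numeric(h) * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
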