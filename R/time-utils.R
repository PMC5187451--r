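# Timestamps are timezone-naive study-local time, represented internally as
# POSIXct in UTC and serialised as "YYYY-MM-DD HH:MM:SS". The participant day
# is anchored at wake time, not midnight.

JITAI_TZ <- "UTC"
JITAI_TS_FMT <- "%Y-%m-%d %H:%M:%S"

parse_ts <- function(x) {
  as.POSIXct(x, tz = JITAI_TZ, format = JITAI_TS_FMT)
}

format_ts <- function(x) {
  format(x, format = JITAI_TS_FMT, tz = JITAI_TZ)
}

# "08:30" -> seconds since midnight
clock_to_sec <- function(clock) {
  parts <- strsplit(clock, ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- as.numeric(p)
    p[1] * 3600 + p[2] * 60 + if (length(p) > 2) p[3] else 0
  }, numeric(1))
}

# date (Date or "YYYY-MM-DD") + clock string -> POSIXct
at_clock <- function(date, clock) {
  as.POSIXct(as.character(as.Date(date)), tz = JITAI_TZ) + clock_to_sec(clock)
}

#' Participant study-day index
#'
#' Day boundaries are anchored at the participant's wake time (the daily diary
#' is tied to waking, so the behavioural day starts at wake, not midnight).
#' Day 1 begins at wake time on the enrollment date.
#'
#' @param at POSIXct timestamp(s).
#' @param enrollment_date Date or string, the first study day.
#' @param wake_time clock string, e.g. `"08:00"`.
#' @return Integer day index (1-based); times before wake on the enrollment
#'   date map to day 0.
#' @export
study_day <- function(at, enrollment_date, wake_time = "08:00") {
  origin <- at_clock(enrollment_date, wake_time)
  as.integer(floor(as.numeric(difftime(at, origin, units = "days"))) + 1L)
}

# internal: run expr with a local RNG state (restores caller's stream)
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# derive a per-unit substream seed below 2^31
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483647)
}
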