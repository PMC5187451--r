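#' Create participant records
#'
#' One row per participant: id, daily waking window, enrollment date, and the
#' derived quit time. The quit attempt is scheduled `prequit_days` after
#' enrollment; with the wake-anchored day convention the postquit phase begins
#' at wake time on day `prequit_days + 1`.
#'
#' @param id Character vector of participant ids.
#' @param wake_time,sleep_time Clock strings (`"HH:MM"`) giving the daily
#'   waking window. Recycled to `length(id)`.
#' @param enrollment_date Date or string; study day 1.
#' @param config A [study_config()].
#' @return A tibble with columns `participant_id`, `wake_time`, `sleep_time`,
#'   `enrollment_date`, `quit_datetime`.
#' @examples
#' participants("P001")
#' @export
participants <- function(id, wake_time = "08:00", sleep_time = "22:00",
                         enrollment_date = "2015-01-01",
                         config = study_config()) {
  stopifnot(length(id) >= 1)
  out <- tibble(
    participant_id = as.character(id),
    wake_time = rep_len(wake_time, length(id)),
    sleep_time = rep_len(sleep_time, length(id)),
    enrollment_date = rep_len(as.Date(enrollment_date), length(id))
  )
  dur_h <- (clock_to_sec(out$sleep_time) - clock_to_sec(out$wake_time)) / 3600
  if (any(dur_h < config$min_waking_hours)) {
    abort(sprintf(
      "Waking window must span at least %g hours (got %.1f).",
      config$min_waking_hours, min(dur_h)
    ))
  }
  out$quit_datetime <- at_clock(
    out$enrollment_date + config$prequit_days, out$wake_time
  )
  out
}

#' Eligibility screen
#'
#' Inclusion flags for the protocol: literacy above sixth-grade equivalent
#' (REALM-SF score >= 4), age >= 18, expired CO >= 8 ppm consistent with
#' current smoking, >= 5 cigarettes/day, and willingness to quit 7 days after
#' the first visit. Instrument content beyond these thresholds is out of
#' scope; only the flags are modelled.
#'
#' @param age,realm_sf,baseline_co_ppm,cigs_per_day Numeric vectors.
#' @param willing_to_quit_7d Logical vector.
#' @return A tibble of per-criterion flags plus an overall `eligible` column.
#' @export
eligibility_flags <- function(age, realm_sf, baseline_co_ppm, cigs_per_day,
                              willing_to_quit_7d) {
  out <- tibble(
    literacy_ok = realm_sf >= 4,
    adult = age >= 18,
    smoking_confirmed = baseline_co_ppm >= 8,
    smokes_5_per_day = cigs_per_day >= 5,
    willing_to_quit_7d = as.logical(willing_to_quit_7d)
  )
  out$eligible <- out$literacy_ok & out$adult & out$smoking_confirmed &
    out$smokes_5_per_day & out$willing_to_quit_7d
  out
}
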