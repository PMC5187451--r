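# Prompt scheduling: one daily diary 30 minutes after waking plus
# n_random_per_day random prompts stratified across the waking window, with a
# minimum gap between prompts; event-contingent follow-ups are queued 15
# minutes after sampled pre-cigarette assessments and About-to-Slip reports.

#' Build one participant-day prompt schedule
#'
#' Places the daily diary at `wake + diary_offset_min` and
#' `n_random_per_day` random prompts within the waking window. Random prompts
#' are drawn by stratified sampling: the window is partitioned into equal
#' strata, one uniform draw per stratum, and the whole draw is rejected and
#' retried if any pair of prompts (including the diary) is closer than
#' `min_gap_min`.
#'
#' @param participant One row of [participants()].
#' @param date Study date (Date or string) within the EMA period.
#' @param config A [study_config()].
#' @param seed Optional integer; when supplied the schedule is a pure
#'   function of `(participant, date, config, seed)`.
#' @return A `DaySchedule` tibble: `participant_id`, `date`, `kind`,
#'   `scheduled_at`, ordered by time.
#' @examples
#' p <- participants("P001", wake_time = "08:00", sleep_time = "22:00")
#' build_day_schedule(p, "2015-01-03", seed = 42)
#' @export
build_day_schedule <- function(participant, date, config = study_config(),
                               seed = NULL) {
  stopifnot(nrow(participant) == 1)
  date <- as.Date(date)
  day0 <- participant$enrollment_date
  n_days <- config$prequit_days + config$postquit_days
  if (date < day0 || date >= day0 + n_days) {
    abort(sprintf(
      "Date %s outside the EMA period [%s, %s).",
      date, day0, day0 + n_days
    ))
  }
  local_seed(seed, {
    wake <- at_clock(date, participant$wake_time)
    sleep <- at_clock(date, participant$sleep_time)
    diary_at <- wake + config$diary_offset_min * 60
    n_rand <- as.integer(config$n_random_per_day)
    gap <- config$min_gap_min * 60
    times <- diary_at
    kinds <- "daily_diary"
    if (n_rand > 0) {
      window <- as.numeric(difftime(sleep, wake, units = "secs"))
      if (window < (n_rand + 1) * gap) {
        abort(paste0(
          "Waking window too short for ", n_rand, " random prompts with a ",
          config$min_gap_min, "-minute gap; reduce `min_gap_min` or ",
          "`n_random_per_day`."
        ))
      }
      bounds <- seq(0, window, length.out = n_rand + 1)
      rand_at <- NULL
      for (attempt in seq_len(1000)) {
        draw <- wake + (bounds[-(n_rand + 1)] +
                          runif(n_rand) * diff(bounds))
        all_t <- sort(c(as.numeric(diary_at), as.numeric(draw)))
        if (all(diff(all_t) >= gap)) {
          rand_at <- draw
          break
        }
      }
      if (is.null(rand_at)) {
        abort(paste0(
          "Could not place random prompts with the requested spacing; ",
          "reduce `min_gap_min`."
        ))
      }
      times <- c(times, rand_at)
      kinds <- c(kinds, rep("random", n_rand))
    }
    ord <- order(times)
    tibble(
      participant_id = participant$participant_id,
      date = date,
      kind = kinds[ord],
      scheduled_at = as.POSIXct(round(times[ord]), tz = JITAI_TZ)
    )
  })
}

#' Resolve a prompted assessment
#'
#' The phone cues each prompted assessment for `prompt_window_sec` seconds;
#' a response initiated within the window completes the assessment, anything
#' later (or no response, `latency = NA`) is recorded as missed — missed is
#' final, prompts never re-fire. Completing the items then takes minutes:
#' `completed_at = presented_at + latency + duration`.
#'
#' @param prompt One schedule row (`participant_id`, `kind`, `scheduled_at`).
#' @param response_latency_sec Seconds from cue to response initiation;
#'   `NA` for no response.
#' @param config A [study_config()].
#' @param duration_min Minutes spent answering (used only when completed).
#' @param origin `"prompted"` for diary/random prompts, `"system_followup"`
#'   for post-cigarette and slip follow-ups (the answer window applies
#'   uniformly).
#' @return A one-row event-log tibble with `status` `"completed"` or
#'   `"missed"`.
#' @examples
#' p <- participants("P001")
#' sched <- build_day_schedule(p, "2015-01-02", seed = 1)
#' resolve_prompt(sched[1, ], response_latency_sec = 59)$status
#' resolve_prompt(sched[1, ], response_latency_sec = 61)$status
#' @export
resolve_prompt <- function(prompt, response_latency_sec = NA,
                           config = study_config(), duration_min = 3,
                           origin = "prompted") {
  if (!is.na(response_latency_sec) && response_latency_sec < 0) {
    abort("`response_latency_sec` must be nonnegative (or NA for no response).")
  }
  completed <- !is.na(response_latency_sec) &&
    response_latency_sec <= config$prompt_window_sec
  presented <- prompt$scheduled_at
  ema_record(
    participant_id = prompt$participant_id,
    kind = prompt$kind,
    origin = origin,
    status = if (completed) "completed" else "missed",
    scheduled_at = prompt$scheduled_at,
    presented_at = presented,
    completed_at = if (completed) {
      presented + response_latency_sec + duration_min * 60
    } else {
      NA
    },
    latency_sec = if (completed) response_latency_sec else NA_real_,
    ema_id = paste0(prompt$participant_id, "-", format(presented, "%Y%m%d%H%M%S"),
                    "-", prompt$kind)
  )
}

#' Per-day smoking-occasion sampling state
#'
#' Tracks, per participant-day, how many smoking occasions have been sampled
#' for full assessment, and the queue of pending system follow-ups
#' (post-cigarette and slip follow-ups) with their due times.
#'
#' @return A `jitai_sampling_state` list with `sampled` (named integer vector
#'   keyed by day) and `pending` (tibble of `kind`, `due_at`).
#' @export
sampling_state <- function() {
  structure(
    list(
      sampled = integer(),
      pending = tibble(kind = character(),
                       due_at = as.POSIXct(character(), tz = JITAI_TZ))
    ),
    class = "jitai_sampling_state"
  )
}

#' Register a prequit "Record Cigarette" button press
#'
#' During the prequit week participants log each cigarette immediately before
#' smoking. To cap assessment burden at most `max_sampled_cigs_per_day`
#' occasions per participant-day are sampled for the full pre-cigarette
#' assessment; while under the cap each logged occasion is sampled with
#' probability `p_sample` (default 1: sample every occasion until the cap).
#' A sampled occasion presents the pre-cigarette assessment immediately and
#' queues the post-cigarette follow-up `postcig_delay_min` minutes after the
#' pre-cigarette assessment completes. The cap counts completed pre-cigarette
#' assessments.
#'
#' @param participant One row of [participants()].
#' @param at POSIXct press time (taken as the pre-cigarette assessment
#'   completion time).
#' @param state A [sampling_state()].
#' @param config A [study_config()].
#' @return List with `sampled` (logical), `followup_due` (POSIXct or `NULL`)
#'   and the updated `state`. Presses in the postquit period are rejected
#'   with an advisory (use the urge/slip buttons instead).
#' @export
register_precig_event <- function(participant, at, state,
                                  config = study_config()) {
  stopifnot(inherits(state, "jitai_sampling_state"))
  if (at >= participant$quit_datetime) {
    warn(paste0(
      "Record Cigarette pressed in the postquit period; event rejected. ",
      "Use the Urge / About to Slip / Already Slipped buttons after quitting."
    ))
    return(list(sampled = FALSE, followup_due = NULL, state = state))
  }
  day <- as.character(study_day(at, participant$enrollment_date,
                                participant$wake_time))
  count <- state$sampled[day]
  if (is.na(count)) count <- 0L
  sampled <- FALSE
  followup_due <- NULL
  if (count < config$max_sampled_cigs_per_day &&
      runif(1) <= config$p_sample) {
    sampled <- TRUE
    state$sampled[day] <- count + 1L
    followup_due <- at + config$postcig_delay_min * 60
    state$pending <- bind_rows(
      state$pending,
      tibble(kind = "postcig", due_at = followup_due)
    )
  }
  list(sampled = sampled, followup_due = followup_due, state = state)
}

#' Register a postquit self-initiated event
#'
#' Postquit participants press "Urge", "About to Slip" or "Already Slipped";
#' each press presents the corresponding assessment immediately. An
#' About-to-Slip assessment is followed by a second assessment
#' `slip_followup_delay_min` minutes later to check whether the participant
#' actually smoked; urge and Already-Slipped assessments queue nothing.
#'
#' @param kind One of `"urge"`, `"about_to_slip"`, `"already_slipped"`.
#' @param at POSIXct press time.
#' @param state A [sampling_state()].
#' @param config A [study_config()].
#' @param participant Optional [participants()] row; when supplied the press
#'   must fall in the postquit period.
#' @return List with `followup_due` (POSIXct or `NULL`) and updated `state`.
#' @export
register_slip_event <- function(kind, at, state, config = study_config(),
                                participant = NULL) {
  kind <- match.arg(kind, c("urge", "about_to_slip", "already_slipped"))
  stopifnot(inherits(state, "jitai_sampling_state"))
  if (!is.null(participant) && at < participant$quit_datetime) {
    abort("Urge/slip buttons are postquit features; use Record Cigarette before the quit date.")
  }
  followup_due <- NULL
  if (kind == "about_to_slip") {
    followup_due <- at + config$slip_followup_delay_min * 60
    state$pending <- bind_rows(
      state$pending,
      tibble(kind = "slip_followup", due_at = followup_due)
    )
  }
  list(followup_due = followup_due, state = state)
}
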