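# The tailored-message decision algorithm: every completed EMA maps to
# exactly one automated message at one of four levels.
#
#   L0  prequit (untailored, predetermined order) and the postquit case where
#       the participant lapsed and is no longer interested in quitting
#   L1  postquit, low imminent lapse risk: motivation / general advice
#   L2  postquit escalation: high imminent risk, or smoked today/yesterday,
#       or daily-diary smoking likelihood strictly above the threshold, or a
#       participant-initiated urge/slip assessment; tailored to the highest
#       rated current lapse trigger
#   L3  the first EMA recording a new lapse: encourage return to abstinence

LEVELS <- c("L0", "L1", "L2", "L3")

#' Classify the message level for a completed EMA
#'
#' Applies the level rules with a fixed precedence:
#' (1) prequit phase -> L0; (2) lapsed and no longer interested in quitting
#' -> L0; (3) first EMA recording a new lapse -> L3; (4) high imminent risk,
#' or smoked that participant-day or the day before, or today's daily-diary
#' smoking likelihood strictly above `diary_risk_threshold_pct`, or an
#' urge/About-to-Slip/Already-Slipped assessment -> L2; (5) otherwise L1.
#'
#' @param context Data frame of context features (vectorised over rows):
#'   `phase` (`"prequit"`/`"postquit"`), `ema_kind`, `high_risk`,
#'   `smoked_today_or_yesterday`, `diary_likelihood_today_pct` (NA when no
#'   diary was completed today), `lapsed_and_uninterested`,
#'   `new_lapse_event`. Usually built by [derive_contexts()].
#' @param config A [study_config()].
#' @return Character vector of levels `"L0"`..`"L3"`.
#' @export
classify_level <- function(context, config = study_config()) {
  stopifnot(all(context$phase %in% c("prequit", "postquit")))
  postquit_only <- c("high_risk", "smoked_today_or_yesterday",
                     "lapsed_and_uninterested", "new_lapse_event")
  pre <- context$phase == "prequit"
  for (nm in postquit_only) {
    if (any(pre & !is.na(context[[nm]]) & context[[nm]] != FALSE)) {
      abort(paste0("Prequit context rows must not set postquit field `", nm, "`."))
    }
  }
  flag <- function(x) !is.na(x) & x
  dl <- context$diary_likelihood_today_pct
  escalate <- flag(context$high_risk) |
    flag(context$smoked_today_or_yesterday) |
    (!is.na(dl) & dl > config$diary_risk_threshold_pct) |
    context$ema_kind %in% c("urge", "about_to_slip", "already_slipped")
  dplyr::case_when(
    pre ~ "L0",
    flag(context$lapsed_and_uninterested) ~ "L0",
    flag(context$new_lapse_event) ~ "L3",
    escalate ~ "L2",
    .default = "L1"
  )
}

#' Select the Level-2 lapse trigger
#'
#' Level-2 messages are tailored to the highest rated of the four current
#' lapse triggers: elevated negative affect/stress, elevated smoking urge,
#' easy access to cigarettes, and low motivation to quit. Motivation enters
#' as `scale_max - motivation_to_quit` so that "low motivation" competes on
#' the same high-is-bad axis. Ties are broken by the fixed preference order
#' negative affect/stress, urge, availability, motivation.
#'
#' @param items Data frame with `urge`, `negative_affect_stress`,
#'   `cigarette_availability`, `motivation_to_quit`; vectorised over rows.
#' @param scale_max Top of the item scale (default 10).
#' @return Character vector in
#'   `c("stress_affect", "urge", "availability", "motivation")`.
#' @examples
#' select_trigger(tibble::tibble(
#'   urge = 4, negative_affect_stress = 4,
#'   cigarette_availability = 1, motivation_to_quit = 10
#' ))
#' @export
select_trigger <- function(items, scale_max = 10) {
  intensities <- cbind(
    stress_affect = items$negative_affect_stress,
    urge = items$urge,
    availability = items$cigarette_availability,
    motivation = scale_max - items$motivation_to_quit
  )
  # columns are already in priority order; max.col(ties.method = "first")
  # therefore implements argmax with the stated tie-break
  TRIGGERS_PRIORITY <- c("stress_affect", "urge", "availability", "motivation")
  TRIGGERS_PRIORITY[max.col(intensities, ties.method = "first")]
}

#' Message-delivery cursor state
#'
#' Tracks, per participant and bank slot, how many messages have been
#' delivered, so that Level-0 prequit messages follow the bank's
#' predetermined order cyclically and Level 1-3 slots rotate round-robin
#' (which never repeats a message back-to-back when a slot has two or more
#' entries).
#'
#' @return An empty `jitai_message_state` (named integer vector).
#' @export
message_state <- function() {
  structure(integer(), class = "jitai_message_state")
}

#' Draw the next message for a slot
#'
#' @param level `"L0"`..`"L3"`.
#' @param trigger A Level-2 trigger, or `"none"` for other levels.
#' @param bank A [load_message_bank()] bank.
#' @param state A [message_state()].
#' @param participant_id,at,source_ema_id Fields stamped onto the emitted
#'   message event.
#' @return List with `event` (one-row message tibble: `participant_id`, `at`,
#'   `level`, `trigger`, `message_id`, `text`, `source_ema_id`) and the
#'   updated `state`.
#' @export
next_message <- function(level, trigger, bank, state,
                         participant_id = "P000", at = NA,
                         source_ema_id = NA_character_) {
  stopifnot(level %in% LEVELS)
  if ((level == "L2") != (trigger != "none")) {
    abort("`trigger` must be a lapse trigger iff level is L2.")
  }
  slot <- bank_slot(bank, level, trigger)
  if (!nrow(slot)) {
    abort(paste0("Message bank has no entries for slot ", level, "/", trigger, "."))
  }
  key <- paste(participant_id, level, trigger, sep = ".")
  count <- state[key]
  if (is.na(count)) count <- 0L
  idx <- (count %% nrow(slot)) + 1L
  state[key] <- count + 1L
  class(state) <- "jitai_message_state"
  event <- tibble(
    participant_id = participant_id,
    at = if (inherits(at, "POSIXct")) at else parse_ts(as.character(at)),
    level = level,
    trigger = trigger,
    message_id = slot$message_id[idx],
    text = slot$text[idx],
    source_ema_id = source_ema_id
  )
  list(event = event, state = state)
}

#' Prequit countdown message
#'
#' During the prequit week the app shares, once a day, the number of days
#' until the scheduled quit attempt ("You are scheduled to quit smoking in
#' 5 DAYS ..."). Days remaining are the ceiling of the time to the quit
#' moment; the scheduler does not call this on or after the quit day.
#'
#' @param now POSIXct current time (prequit).
#' @param quit_datetime POSIXct scheduled quit moment.
#' @return The message text, containing `"<n> DAYS"` (or `"1 DAY"`).
#' @examples
#' countdown_message(as.POSIXct("2015-01-03 09:00:00", tz = "UTC"),
#'                   as.POSIXct("2015-01-08 08:00:00", tz = "UTC"))
#' @export
countdown_message <- function(now, quit_datetime) {
  if (now >= quit_datetime) {
    abort("Countdown messages are a prequit feature; `now` is past the quit time.")
  }
  days <- ceiling(as.numeric(difftime(quit_datetime, now, units = "days")))
  sprintf(
    paste0(
      "You are scheduled to quit smoking in %d %s. Developing a plan to ",
      "quit and taking your medications will GREATLY increase your chances ",
      "for staying quit."
    ),
    days, if (days == 1) "DAY" else "DAYS"
  )
}

#' Log an on-demand feature use
#'
#' Appends an on-demand record to the event log: Quit Tips (five categories),
#' Medication Tips (four medications), the one-click quitline call stub
#' ("Phone a Counselor"), the study-staff call stub, and the payment view.
#' A payment view computes the up-to-the-moment compensation from the
#' prompted EMAs in the log via [compute_compensation()] and attaches it as
#' the `"compensation"` attribute of the returned log.
#'
#' @param events Event-log tibble to append to.
#' @param participant_id Participant id.
#' @param kind One of `"quit_tips"`, `"medication_tips"`,
#'   `"phone_counselor"`, `"call_staff"`, `"payment_view"`.
#' @param at POSIXct access time.
#' @param category Tip category (required for quit/medication tips).
#' @param n_tips_viewed Number of tips viewed on this occasion (viewing
#'   intensity).
#' @param config A [study_config()].
#' @return The updated event log (invisibly carries attribute
#'   `"compensation"` after a payment view).
#' @export
record_on_demand <- function(events, participant_id, kind, at,
                             category = NA_character_,
                             n_tips_viewed = NA_integer_,
                             config = study_config()) {
  kind <- match.arg(kind, ON_DEMAND_KINDS)
  valid <- switch(kind,
    quit_tips = QUIT_TIP_CATEGORIES,
    medication_tips = MEDICATION_CATEGORIES,
    NA_character_
  )
  if (kind %in% c("quit_tips", "medication_tips")) {
    if (is.na(category) || !category %in% valid) {
      abort(paste0(
        "Unknown ", kind, " category `", category, "`; expected one of: ",
        paste(valid, collapse = ", ")
      ))
    }
  } else {
    category <- NA_character_
  }
  row <- empty_event_log()[0, ]
  row <- tibble(
    record_type = "on_demand",
    ema_id = NA_character_,
    participant_id = as.character(participant_id),
    kind = kind,
    origin = NA_character_,
    scheduled_at = as.POSIXct(NA_character_, tz = JITAI_TZ),
    presented_at = if (inherits(at, "POSIXct")) at else parse_ts(as.character(at)),
    completed_at = as.POSIXct(NA_character_, tz = JITAI_TZ),
    status = NA_character_,
    latency_sec = NA_real_,
    category = category,
    n_tips_viewed = as.integer(n_tips_viewed)
  )
  out <- coerce_event_types(bind_rows(events, row))
  if (kind == "payment_view") {
    prompted <- out[out$record_type == "ema" &
                      out$participant_id == participant_id &
                      !is.na(out$origin) & out$origin == "prompted", ]
    attr(out, "compensation") <- if (nrow(prompted)) {
      compute_compensation(
        completed = sum(prompted$status == "completed"),
        prompted = nrow(prompted),
        config = config
      )
    } else {
      NA_real_
    }
  }
  out
}
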