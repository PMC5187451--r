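#' Derive decision-engine context features from an event log
#'
#' Recomputes, for every completed EMA, the features the level classifier
#' needs, from the event log alone: phase relative to the participant's quit
#' time; whether any lapse is on record for the current participant-day or
#' the day before (wake-anchored day boundary; a lapse record is an
#' Already-Slipped assessment, a slip follow-up confirming smoking, or any
#' postquit `smoked_since_last = TRUE` answer, including the current one);
#' whether the current EMA records a *new* lapse (an Already-Slipped or
#' smoking-confirming slip follow-up with no lapse already on record for
#' today or yesterday); today's daily-diary smoking likelihood (NA when no
#' diary was completed today); whether the participant has lapsed and
#' reports no further interest in quitting; and the lapse-risk score from
#' [estimate_lapse_risk()] (postquit only).
#'
#' @param events Event-log tibble.
#' @param participants A [participants()] tibble covering every participant
#'   in the log.
#' @param config A [study_config()].
#' @return One context row per completed EMA: `ema_id`, `participant_id`,
#'   `at`, `phase`, `ema_kind`, the four tailoring items, `score`,
#'   `high_risk`, `smoked_today_or_yesterday`, `diary_likelihood_today_pct`,
#'   `lapsed_and_uninterested`, `new_lapse_event`.
#' @export
derive_contexts <- function(events, participants, config = study_config()) {
  comp <- events[events$record_type == "ema" & events$status == "completed", ]
  if (!nrow(comp)) {
    return(tibble(
      ema_id = character(), participant_id = character(),
      at = as.POSIXct(character(), tz = JITAI_TZ),
      phase = character(), ema_kind = character(),
      urge = integer(), negative_affect_stress = integer(),
      cigarette_availability = integer(), motivation_to_quit = integer(),
      score = numeric(), high_risk = logical(),
      smoked_today_or_yesterday = logical(),
      diary_likelihood_today_pct = integer(),
      lapsed_and_uninterested = logical(), new_lapse_event = logical()
    ))
  }
  missing_p <- setdiff(unique(comp$participant_id), participants$participant_id)
  if (length(missing_p)) {
    abort(paste0(
      "Event log has participants without a participant record: ",
      paste(head(missing_p, 3), collapse = ", ")
    ))
  }
  out <- vector("list", length(unique(comp$participant_id)))
  pids <- unique(comp$participant_id)
  for (pi in seq_along(pids)) {
    pid <- pids[pi]
    p <- participants[participants$participant_id == pid, ][1, ]
    rows <- comp[comp$participant_id == pid, ]
    rows <- rows[order(rows$completed_at), ]
    n <- nrow(rows)
    day <- study_day(rows$completed_at, p$enrollment_date, p$wake_time)
    post <- rows$completed_at >= p$quit_datetime
    smoked_ans <- !is.na(rows$smoked_since_last) & rows$smoked_since_last
    reports_smoke <- post & (rows$kind == "already_slipped" | smoked_ans)
    reports_lapse_kind <- post & (rows$kind == "already_slipped" |
                                    (rows$kind == "slip_followup" & smoked_ans))
    smoked_ty <- logical(n)
    new_lapse <- logical(n)
    lapsed_any <- logical(n)
    diary_today <- rep(NA_integer_, n)
    lapse_days <- integer()
    last_diary_day <- NA_integer_
    last_diary_val <- NA_integer_
    for (i in seq_len(n)) {
      prior_ty <- any(lapse_days %in% c(day[i], day[i] - 1L))
      smoked_ty[i] <- prior_ty || reports_smoke[i]
      new_lapse[i] <- reports_lapse_kind[i] && !prior_ty
      if (rows$kind[i] == "daily_diary" &&
          !is.na(rows$diary_smoking_likelihood_pct[i])) {
        last_diary_day <- day[i]
        last_diary_val <- rows$diary_smoking_likelihood_pct[i]
      }
      diary_today[i] <- if (!is.na(last_diary_day) && last_diary_day == day[i]) {
        last_diary_val
      } else {
        NA_integer_
      }
      lapsed_any[i] <- length(lapse_days) > 0 || reports_smoke[i]
      if (reports_smoke[i]) lapse_days <- union(lapse_days, day[i])
    }
    uninterested <- !is.na(rows$still_interested_in_quitting) &
      !rows$still_interested_in_quitting
    risk <- estimate_lapse_risk(rows, spec = config$risk_estimator,
                                scale_max = config$item_scale_max)
    out[[pi]] <- tibble(
      ema_id = rows$ema_id,
      participant_id = pid,
      at = rows$completed_at,
      phase = ifelse(post, "postquit", "prequit"),
      ema_kind = rows$kind,
      urge = rows$urge,
      negative_affect_stress = rows$negative_affect_stress,
      cigarette_availability = rows$cigarette_availability,
      motivation_to_quit = rows$motivation_to_quit,
      score = ifelse(post, risk$score, NA_real_),
      high_risk = ifelse(post, risk$high_risk, NA),
      smoked_today_or_yesterday = ifelse(post, smoked_ty, NA),
      diary_likelihood_today_pct = ifelse(post, diary_today, NA_integer_),
      lapsed_and_uninterested = ifelse(post, lapsed_any & uninterested, NA),
      new_lapse_event = ifelse(post, new_lapse, NA)
    )
  }
  bind_rows(out)
}

#' Replay an event log through the decision engine
#'
#' Deterministically maps every completed EMA in the log to exactly one
#' automated message: derives context features ([derive_contexts()]),
#' classifies the level ([classify_level()]), tailors Level-2 messages to
#' the highest rated lapse trigger ([select_trigger()]), and draws message
#' content from the bank — Level-0 prequit messages in the bank's
#' predetermined order cyclically, other slots round-robin.
#'
#' @param events Event-log tibble.
#' @param participants A [participants()] tibble.
#' @param bank A [load_message_bank()] bank.
#' @param config A [study_config()].
#' @return A message tibble: one row per completed EMA with
#'   `participant_id`, `at`, `level`, `trigger`, `message_id`, `text`,
#'   `source_ema_id`.
#' @export
run_engine <- function(events, participants, bank = default_message_bank(),
                       config = study_config()) {
  ctx <- derive_contexts(events, participants, config)
  if (!nrow(ctx)) {
    return(tibble(
      participant_id = character(),
      at = as.POSIXct(character(), tz = JITAI_TZ),
      level = character(), trigger = character(),
      message_id = character(), text = character(),
      source_ema_id = character()
    ))
  }
  ctx$level <- classify_level(ctx, config)
  ctx$trigger <- ifelse(
    ctx$level == "L2",
    select_trigger(ctx, scale_max = config$item_scale_max),
    "none"
  )
  slot_bank <- bank |>
    as_tibble() |>
    group_by(.data$level, .data$trigger_or_category) |>
    mutate(slot_idx = dplyr::row_number() - 1L, slot_n = dplyr::n()) |>
    ungroup()
  msgs <- ctx |>
    arrange(.data$participant_id, .data$at) |>
    group_by(.data$participant_id, .data$level, .data$trigger) |>
    mutate(slot_idx = (dplyr::row_number() - 1L) %% slot_n_for(
      .data$level[1], .data$trigger[1], slot_bank
    )) |>
    ungroup() |>
    left_join(
      slot_bank |>
        select("level", trigger = "trigger_or_category", "slot_idx",
               "message_id", "text"),
      by = c("level", "trigger", "slot_idx")
    )
  if (any(is.na(msgs$message_id))) {
    bad <- msgs[is.na(msgs$message_id), c("level", "trigger")][1, ]
    abort(paste0(
      "Message bank has no entries for slot ", bad$level, "/", bad$trigger, "."
    ))
  }
  msgs |>
    transmute(
      .data$participant_id, .data$at, .data$level, .data$trigger,
      .data$message_id, .data$text, source_ema_id = .data$ema_id
    ) |>
    arrange(.data$participant_id, .data$at)
}

slot_n_for <- function(level, trigger, slot_bank) {
  n <- slot_bank$slot_n[slot_bank$level == level &
                          slot_bank$trigger_or_category == trigger][1]
  if (is.na(n)) {
    abort(paste0("Message bank has no entries for slot ", level, "/", trigger, "."))
  }
  n
}
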