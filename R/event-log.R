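# Event-log schema ------------------------------------------------------------
#
# One flat tibble holds both EMA records and on-demand feature-use records
# (record_type "ema" / "on_demand"); messages produced by the decision engine
# live in their own tibble. On disk the log is JSONL: one record per line,
# append- and diff-friendly.

EMA_KINDS <- c(
  "daily_diary", "random", "precig", "postcig",
  "urge", "about_to_slip", "slip_followup", "already_slipped"
)
ON_DEMAND_KINDS <- c(
  "quit_tips", "medication_tips", "phone_counselor", "call_staff",
  "payment_view"
)
EMA_ORIGINS <- c("prompted", "self_initiated", "system_followup")
EMA_STATUSES <- c("pending", "completed", "missed")
PROMPTED_KINDS <- c("daily_diary", "random")

QUIT_TIP_CATEGORIES <- c(
  "general_advice", "benefits", "coping_urges", "coping_stress", "coping_mood"
)
MEDICATION_CATEGORIES <- c("varenicline", "patch", "gum", "bupropion")

ITEM_COLS <- c(
  "urge", "negative_affect_stress", "cigarette_availability",
  "motivation_to_quit", "smoked_since_last", "diary_smoking_likelihood_pct",
  "still_interested_in_quitting", "alcohol_last_24h"
)

#' Empty event log
#'
#' Returns a zero-row tibble with the full event-log schema, used as the
#' starting point for appending records.
#'
#' @return A zero-row event-log tibble.
#' @export
empty_event_log <- function() {
  tibble(
    record_type = character(),
    ema_id = character(),
    participant_id = character(),
    kind = character(),
    origin = character(),
    scheduled_at = as.POSIXct(character(), tz = JITAI_TZ),
    presented_at = as.POSIXct(character(), tz = JITAI_TZ),
    completed_at = as.POSIXct(character(), tz = JITAI_TZ),
    status = character(),
    latency_sec = numeric(),
    category = character(),
    n_tips_viewed = integer(),
    urge = integer(),
    negative_affect_stress = integer(),
    cigarette_availability = integer(),
    motivation_to_quit = integer(),
    smoked_since_last = logical(),
    diary_smoking_likelihood_pct = integer(),
    still_interested_in_quitting = logical(),
    alcohol_last_24h = logical()
  )
}

#' Construct EMA records
#'
#' Builds one or more EMA rows in event-log schema. Prompted and
#' system-follow-up records carry a `scheduled_at`; self-initiated records
#' must not (they exist only once the participant starts them).
#'
#' @param participant_id,kind,origin,status Character vectors.
#' @param scheduled_at,presented_at,completed_at POSIXct or `NA`.
#' @param latency_sec Seconds from cue to response initiation (`NA` if missed).
#' @param ema_id Record id; autogenerated when `NULL`.
#' @param ... Item responses (`urge`, `negative_affect_stress`,
#'   `cigarette_availability`, `motivation_to_quit`, `smoked_since_last`,
#'   `diary_smoking_likelihood_pct`, `still_interested_in_quitting`,
#'   `alcohol_last_24h`).
#' @return An event-log tibble.
#' @export
ema_record <- function(participant_id, kind, origin, status,
                       scheduled_at = NA, presented_at = NA, completed_at = NA,
                       latency_sec = NA_real_, ema_id = NULL, ...) {
  items <- list(...)
  bad <- setdiff(names(items), ITEM_COLS)
  if (length(bad)) {
    abort(paste0("Unknown item field(s): ", paste(bad, collapse = ", ")))
  }
  n <- max(length(participant_id), length(kind))
  row <- tibble(
    record_type = "ema",
    ema_id = ema_id %||% sprintf(
      "%s-%s", rep_len(as.character(participant_id), n),
      vapply(seq_len(n), function(i) {
        sprintf("%08x", as.integer(stats::runif(1, 0, 2^30)))
      }, character(1))
    ),
    participant_id = rep_len(as.character(participant_id), n),
    kind = rep_len(kind, n),
    origin = rep_len(origin, n),
    scheduled_at = as_ts_col(scheduled_at, n),
    presented_at = as_ts_col(presented_at, n),
    completed_at = as_ts_col(completed_at, n),
    status = rep_len(status, n),
    latency_sec = rep_len(as.numeric(latency_sec), n),
    category = NA_character_,
    n_tips_viewed = NA_integer_
  )
  for (nm in ITEM_COLS) {
    row[[nm]] <- if (nm %in% names(items)) rep_len(items[[nm]], n) else NA
  }
  coerce_event_types(bind_rows(empty_event_log(), row))
}

as_ts_col <- function(x, n) {
  if (inherits(x, "POSIXct")) return(rep_len(x, n))
  if (all(is.na(x))) {
    return(rep_len(as.POSIXct(NA_character_, tz = JITAI_TZ), n))
  }
  rep_len(parse_ts(as.character(x)), n)
}

coerce_event_types <- function(df) {
  for (nm in setdiff(names(empty_event_log()), names(df))) df[[nm]] <- NA
  int_cols <- c(
    "n_tips_viewed", "urge", "negative_affect_stress",
    "cigarette_availability", "motivation_to_quit",
    "diary_smoking_likelihood_pct"
  )
  for (nm in int_cols) df[[nm]] <- as.integer(df[[nm]])
  for (nm in c("smoked_since_last", "still_interested_in_quitting",
               "alcohol_last_24h")) {
    df[[nm]] <- as.logical(df[[nm]])
  }
  df$latency_sec <- as.numeric(df$latency_sec)
  df
}

#' Validate an event log
#'
#' Checks the structural invariants of the log: known kinds, origins and
#' statuses; completed EMA records carry item responses; missed records carry
#' none; self-initiated records have no `scheduled_at`; prompted completed
#' records responded within the prompt window; item scores within the declared
#' scales; diary likelihood present only on daily diaries.
#'
#' @param events Event-log tibble.
#' @param config A [study_config()].
#' @return `events`, invisibly; aborts with an informative message on the
#'   first violated invariant.
#' @export
validate_events <- function(events, config = study_config()) {
  ema <- events[events$record_type == "ema", ]
  bad_kind <- setdiff(unique(events$kind), c(EMA_KINDS, ON_DEMAND_KINDS))
  if (length(bad_kind)) {
    abort(paste0("Unknown event kind(s): ", paste(bad_kind, collapse = ", ")))
  }
  if (nrow(ema)) {
    if (!all(ema$origin %in% EMA_ORIGINS)) abort("Unknown EMA origin.")
    if (!all(ema$status %in% EMA_STATUSES)) abort("Unknown EMA status.")
    comp <- ema[ema$status == "completed", ]
    if (any(is.na(comp$urge))) {
      abort("Completed EMA records must carry item responses (missing `urge`).")
    }
    missed <- ema[ema$status == "missed", ]
    if (nrow(missed) && any(!is.na(missed$urge))) {
      abort("Missed EMA records must have empty item responses.")
    }
    selfi <- ema[ema$origin == "self_initiated", ]
    if (nrow(selfi) && any(!is.na(selfi$scheduled_at))) {
      abort("Self-initiated records must not carry `scheduled_at`.")
    }
    prompted_comp <- comp[comp$origin %in% c("prompted", "system_followup"), ]
    if (nrow(prompted_comp) &&
        any(prompted_comp$latency_sec > config$prompt_window_sec, na.rm = TRUE)) {
      abort("Completed prompted records must respond within the prompt window.")
    }
    smax <- config$item_scale_max
    for (nm in c("urge", "negative_affect_stress", "cigarette_availability",
                 "motivation_to_quit")) {
      v <- comp[[nm]]
      if (any(v < 0 | v > smax, na.rm = TRUE)) {
        abort(paste0("Item `", nm, "` outside 0-", smax, " scale."))
      }
    }
    dl <- comp$diary_smoking_likelihood_pct
    if (any(dl < 0 | dl > config$diary_scale_max, na.rm = TRUE)) {
      abort("Diary smoking likelihood outside its scale.")
    }
    if (any(!is.na(dl) & comp$kind != "daily_diary")) {
      abort("`diary_smoking_likelihood_pct` is a daily-diary item only.")
    }
  }
  od <- events[events$record_type == "on_demand", ]
  if (nrow(od) && !all(od$kind %in% ON_DEMAND_KINDS)) {
    abort("Unknown on-demand kind.")
  }
  invisible(events)
}

# JSONL serialisation ----------------------------------------------------------

#' Write an event log to JSONL
#'
#' One JSON object per line; `NA` fields are omitted; timestamps are
#' serialised as `"YYYY-MM-DD HH:MM:SS"` study-local strings. The round trip
#' through [read_event_log()] is lossless.
#'
#' @param events Event-log tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(events, path) {
  df <- events
  for (nm in c("scheduled_at", "presented_at", "completed_at")) {
    df[[nm]] <- format_ts(df[[nm]])
  }
  lines <- vapply(seq_len(nrow(df)), function(i) {
    rec <- as.list(df[i, ])
    rec <- rec[!vapply(rec, function(v) is.na(v) || is.null(v), logical(1))]
    jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an event log from JSONL
#'
#' Parses one record per line, validates the vocabulary (unknown kinds are
#' reported with their line number), and returns records sorted by timestamp
#' within participant, warning if the file was out of order.
#'
#' @param path JSONL file path.
#' @param config A [study_config()] used for validation.
#' @return An event-log tibble.
#' @export
read_event_log <- function(path, config = study_config()) {
  if (!file.exists(path)) abort(paste0("Event log not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_event_log())
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]]),
      error = function(e) {
        abort(sprintf("Line %d: could not parse JSON (%s)", i, conditionMessage(e)))
      }
    )
    if (is.null(rec$kind) ||
        !rec$kind %in% c(EMA_KINDS, ON_DEMAND_KINDS)) {
      abort(sprintf("Line %d: unknown event kind `%s`", i, rec$kind %||% "<missing>"))
    }
    recs[[i]] <- as_tibble(rec[!vapply(rec, is.null, logical(1))])
  }
  df <- bind_rows(recs)
  for (nm in c("scheduled_at", "presented_at", "completed_at")) {
    df[[nm]] <- if (nm %in% names(df)) parse_ts(as.character(df[[nm]])) else NA
  }
  df <- coerce_event_types(bind_rows(empty_event_log(), df))
  key <- order(df$participant_id, event_time(df))
  if (!identical(key, seq_len(nrow(df)))) {
    warn("Event log was out of order; records sorted by participant and time.")
    df <- df[key, ]
  }
  validate_events(df, config)
  df
}

# canonical ordering time: first available of presented/completed/scheduled
event_time <- function(events) {
  t <- events$presented_at
  t[is.na(t)] <- events$completed_at[is.na(t)]
  t[is.na(t)] <- events$scheduled_at[is.na(t)]
  t
}

# Visit tables -----------------------------------------------------------------

VISIT_LEVELS <- c("quit_date", "wk1", "wk2", "wk3", "wk4", "wk12")

#' Read / write a follow-up visit table
#'
#' CSV with columns `participant_id`, `visit` (one of quit_date, wk1, wk2,
#' wk3, wk4, wk12), `attended`, `self_report_abstinent`, `co_ppm`. A missed
#' visit must have null self-report and CO.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_visit_table <- function(path) {
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      visit = readr::col_character(),
      attended = readr::col_logical(),
      self_report_abstinent = readr::col_logical(),
      co_ppm = readr::col_double()
    )
  )
  bad <- setdiff(unique(df$visit), VISIT_LEVELS)
  if (length(bad)) {
    abort(paste0("Unknown visit label(s): ", paste(bad, collapse = ", ")))
  }
  if (any(!df$attended & (!is.na(df$self_report_abstinent) | !is.na(df$co_ppm)))) {
    abort("Missed visits must have null self-report and CO fields.")
  }
  df
}

#' @rdname read_visit_table
#' @param visits Visit tibble.
#' @export
write_visit_table <- function(visits, path) {
  readr::write_csv(visits, path)
  invisible(path)
}
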