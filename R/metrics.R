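#' Compute EMA-based compensation
#'
#' Compensation is tiered on the fraction of prompted EMAs completed over the
#' 3-week period: below 50% earns nothing, 50%-74% a USD 40 gift card,
#' 75%-89% USD 80, and 90% or more USD 120. The printed integer-percent
#' ranges are implemented on the real-valued fraction with half-open
#' intervals at 0.50 / 0.75 / 0.90, so every fraction maps to exactly one
#' tier and the amount is monotone nondecreasing.
#'
#' @param completed,prompted Counts (vectorised); `0 <= completed <= prompted`,
#'   `prompted > 0`.
#' @param config A [study_config()] carrying `compensation_tiers`.
#' @return USD amount(s).
#' @examples
#' compute_compensation(95, 105)  # 0.905 -> 120
#' compute_compensation(63, 105)  # 0.60  -> 40
#' @export
compute_compensation <- function(completed, prompted, config = study_config()) {
  if (any(prompted <= 0)) {
    abort("`prompted` must be positive: no prompted EMAs, no completion fraction.")
  }
  if (any(completed < 0) || any(completed > prompted)) {
    abort("`completed` must lie in [0, prompted].")
  }
  f <- completed / prompted
  bounds <- vapply(config$compensation_tiers, function(t) t$min_fraction,
                   numeric(1))
  amounts <- c(0, vapply(config$compensation_tiers, function(t) as.numeric(t$usd),
                         numeric(1)))
  amounts[findInterval(f, bounds) + 1L]
}

#' Per-participant compensation table
#'
#' @param events Event-log tibble.
#' @param config A [study_config()].
#' @return Tibble with `participant_id`, `prompted`, `completed`, `fraction`,
#'   `usd`.
#' @export
compensation_report <- function(events, config = study_config()) {
  events |>
    filter(.data$record_type == "ema", !is.na(.data$origin),
           .data$origin == "prompted") |>
    group_by(.data$participant_id) |>
    summarise(
      prompted = dplyr::n(),
      completed = sum(.data$status == "completed"),
      .groups = "drop"
    ) |>
    mutate(
      fraction = .data$completed / .data$prompted,
      usd = compute_compensation(.data$completed, .data$prompted, config)
    )
}

#' EMA compliance report
#'
#' Summarises prompt adherence: per-kind prompted/completed counts and rates
#' (over prompted-origin records; system follow-ups are tabulated separately
#' and an all-origin rate is also reported), mean minutes to completion
#' (over completed records with both `presented_at` and `completed_at`),
#' per-participant completion fractions, and — when a message table is
#' supplied — the cohort mean messages per participant.
#'
#' @param events Event-log tibble.
#' @param messages Optional message tibble from [run_engine()].
#' @return A `jitai_compliance` list with tibbles `by_kind`, `by_origin`,
#'   `by_participant` and `overall`.
#' @export
compliance_report <- function(events, messages = NULL) {
  ema <- events[events$record_type == "ema", ]
  if (!nrow(ema)) {
    warn("Empty event log; returning an empty compliance report.")
    return(structure(
      list(by_kind = tibble(), by_origin = tibble(),
           by_participant = tibble(), overall = tibble()),
      class = "jitai_compliance"
    ))
  }
  minutes <- as.numeric(difftime(ema$completed_at, ema$presented_at,
                                 units = "mins"))
  ema$completion_min <- ifelse(ema$status == "completed", minutes, NA_real_)
  prompted <- ema[ema$origin == "prompted", ]
  by_kind <- ema |>
    group_by(.data$kind, .data$origin) |>
    summarise(
      n = dplyr::n(),
      n_completed = sum(.data$status == "completed"),
      rate = if (all(.data$origin %in% c("prompted", "system_followup"))) {
        sum(.data$status == "completed") / dplyr::n()
      } else {
        NA_real_
      },
      mean_completion_min = mean(.data$completion_min, na.rm = TRUE),
      .groups = "drop"
    ) |>
    arrange(.data$origin, .data$kind)
  by_participant <- ema |>
    filter(.data$origin == "prompted") |>
    group_by(.data$participant_id) |>
    summarise(
      prompted = dplyr::n(),
      completed = sum(.data$status == "completed"),
      fraction = .data$completed / .data$prompted,
      .groups = "drop"
    )
  n_self <- ema |>
    filter(.data$origin == "self_initiated") |>
    count(.data$participant_id, name = "n_self_initiated")
  by_participant <- by_participant |>
    left_join(n_self, by = "participant_id") |>
    mutate(n_self_initiated = dplyr::coalesce(.data$n_self_initiated, 0L))
  answerable <- ema[ema$origin %in% c("prompted", "system_followup"), ]
  overall <- tibble(
    n_prompted = nrow(prompted),
    n_completed = sum(prompted$status == "completed"),
    completion_rate = if (nrow(prompted)) {
      sum(prompted$status == "completed") / nrow(prompted)
    } else {
      NA_real_
    },
    completion_rate_all_origins = if (nrow(answerable)) {
      sum(answerable$status == "completed") / nrow(answerable)
    } else {
      NA_real_
    },
    mean_self_initiated = if (nrow(by_participant)) {
      mean(by_participant$n_self_initiated)
    } else {
      NA_real_
    },
    mean_messages_per_participant = if (!is.null(messages)) {
      nrow(messages) / dplyr::n_distinct(ema$participant_id)
    } else {
      NA_real_
    }
  )
  structure(
    list(by_kind = by_kind, by_origin = NULL, by_participant = by_participant,
         overall = overall),
    class = "jitai_compliance"
  )
}

#' @export
print.jitai_compliance <- function(x, ...) {
  cat("<jitai compliance report>\n")
  if (nrow(x$overall)) {
    cat(sprintf(
      "  %d/%d prompted EMAs completed (%.1f%%)\n",
      x$overall$n_completed, x$overall$n_prompted,
      100 * x$overall$completion_rate
    ))
    print(x$by_kind)
  }
  invisible(x)
}

#' Tidy / summarise a compliance report
#'
#' @param x A `jitai_compliance`.
#' @param ... Unused.
#' @return `tidy()`: the per-kind table; `glance()`: the one-row overall
#'   summary.
#' @export
tidy.jitai_compliance <- function(x, ...) x$by_kind

#' @rdname tidy.jitai_compliance
#' @export
glance.jitai_compliance <- function(x, ...) x$overall

#' On-demand feature-use report
#'
#' Tabulates on-demand use the way feasibility tables report it: per tip
#' type, the number of participants who used it, the per-user access count
#' (frequency: mean, SD, median) and the tips viewed per occasion
#' (intensity: mean, SD, median). With a prescription table, counts viewers
#' of each medication's tips who were not prescribed it.
#'
#' @param events Event-log tibble.
#' @param prescriptions Optional tibble (`participant_id`, `medication`)
#'   of prescribed cessation medications.
#' @return A `jitai_feature_use` list with `by_category`, `by_kind` and
#'   (optionally) `not_prescribed` tibbles.
#' @export
feature_use_report <- function(events, prescriptions = NULL) {
  od <- events[events$record_type == "on_demand", ]
  template <- tidyr::expand_grid(
    kind = c("quit_tips", "medication_tips"),
    category = NA_character_
  )
  template <- bind_rows(
    tibble(kind = "quit_tips", category = QUIT_TIP_CATEGORIES),
    tibble(kind = "medication_tips", category = MEDICATION_CATEGORIES)
  )
  per_user <- od |>
    filter(.data$kind %in% c("quit_tips", "medication_tips")) |>
    group_by(.data$kind, .data$category, .data$participant_id) |>
    summarise(n_accesses = dplyr::n(), .groups = "drop")
  by_category <- template |>
    left_join(
      per_user |>
        group_by(.data$kind, .data$category) |>
        summarise(
          n_users = dplyr::n(),
          accesses_mean = mean(.data$n_accesses),
          accesses_sd = sd(.data$n_accesses),
          accesses_median = median(.data$n_accesses),
          .groups = "drop"
        ),
      by = c("kind", "category")
    ) |>
    left_join(
      od |>
        filter(.data$kind %in% c("quit_tips", "medication_tips"),
               !is.na(.data$n_tips_viewed)) |>
        group_by(.data$kind, .data$category) |>
        summarise(
          intensity_mean = mean(.data$n_tips_viewed),
          intensity_sd = sd(.data$n_tips_viewed),
          intensity_median = median(.data$n_tips_viewed),
          .groups = "drop"
        ),
      by = c("kind", "category")
    ) |>
    mutate(n_users = dplyr::coalesce(.data$n_users, 0L))
  by_kind <- od |>
    group_by(.data$kind) |>
    summarise(
      n_users = dplyr::n_distinct(.data$participant_id),
      n_accesses = dplyr::n(),
      .groups = "drop"
    )
  not_prescribed <- NULL
  if (!is.null(prescriptions)) {
    not_prescribed <- od |>
      filter(.data$kind == "medication_tips") |>
      distinct(.data$participant_id, medication = .data$category) |>
      anti_join(prescriptions, by = c("participant_id", "medication")) |>
      count(.data$medication, name = "n_viewers_not_prescribed")
  }
  structure(
    list(by_category = by_category, by_kind = by_kind,
         not_prescribed = not_prescribed),
    class = "jitai_feature_use"
  )
}

#' @export
print.jitai_feature_use <- function(x, ...) {
  cat("<jitai on-demand feature-use report>\n")
  print(x$by_category)
  invisible(x)
}

#' @export
tidy.jitai_feature_use <- function(x, ...) x$by_category

#' Classify biochemically verified abstinence
#'
#' A participant is abstinent at a visit iff they attended, self-reported
#' 7-day abstinence ("not even a puff"), *and* the expired-CO reading was
#' strictly below the cutoff: `co_cutoff_quitdate_ppm` (10) on the quit date,
#' `co_cutoff_followup_ppm` (8) at every later visit. A missed visit is
#' nonabstinent; an attended visit without a CO reading is an error
#' (verification is required).
#'
#' @param visits Visit tibble (`participant_id`, `visit`, `attended`,
#'   `self_report_abstinent`, `co_ppm`); vectorised over rows.
#' @param config A [study_config()].
#' @return Logical vector.
#' @examples
#' v <- tibble::tibble(
#'   participant_id = "P001", visit = c("wk4", "wk4", "quit_date"),
#'   attended = TRUE, self_report_abstinent = TRUE, co_ppm = c(7, 8, 9)
#' )
#' classify_abstinence(v)  # TRUE FALSE TRUE
#' @export
classify_abstinence <- function(visits, config = study_config()) {
  if (any(visits$attended & is.na(visits$co_ppm))) {
    abort("Attended visit without a CO reading: biochemical verification is required.")
  }
  cutoff <- ifelse(visits$visit == "quit_date",
                   config$co_cutoff_quitdate_ppm,
                   config$co_cutoff_followup_ppm)
  visits$attended &
    !is.na(visits$self_report_abstinent) & visits$self_report_abstinent &
    visits$co_ppm < cutoff
}

#' Point-prevalence abstinence report
#'
#' Per-visit counts and proportions of verified abstinence. The denominator
#' is the full enrolled cohort, not the attendees: participants who did not
#' attend a visit are counted as nonabstinent.
#'
#' @param visits Visit tibble, one row per participant-visit.
#' @param config A [study_config()].
#' @param n_enrolled Cohort size for the denominator; defaults to the number
#'   of distinct participants in the table.
#' @return A `jitai_abstinence` list: `by_visit` (visit, n_abstinent,
#'   n_enrolled, proportion) and `by_participant` (wide logical table).
#' @export
abstinence_report <- function(visits, config = study_config(),
                              n_enrolled = NULL) {
  if (anyDuplicated(visits[, c("participant_id", "visit")])) {
    abort("Duplicate participant-visit rows in the visit table.")
  }
  n_enrolled <- n_enrolled %||% dplyr::n_distinct(visits$participant_id)
  visits$abstinent <- classify_abstinence(visits, config)
  by_visit <- tibble(visit = intersect(VISIT_LEVELS, unique(visits$visit))) |>
    left_join(
      visits |>
        group_by(.data$visit) |>
        summarise(n_abstinent = sum(.data$abstinent), .groups = "drop"),
      by = "visit"
    ) |>
    mutate(
      n_enrolled = n_enrolled,
      proportion = .data$n_abstinent / n_enrolled
    )
  by_participant <- visits |>
    select("participant_id", "visit", "abstinent") |>
    tidyr::pivot_wider(names_from = "visit", values_from = "abstinent")
  structure(
    list(by_visit = by_visit, by_participant = by_participant),
    class = "jitai_abstinence"
  )
}

#' @export
print.jitai_abstinence <- function(x, ...) {
  cat("<jitai point-prevalence abstinence report>\n")
  print(x$by_visit)
  invisible(x)
}

#' @export
tidy.jitai_abstinence <- function(x, ...) x$by_visit
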