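#' Plot a compliance report
#'
#' Bar chart of per-kind completion rates for prompted and system-follow-up
#' assessments.
#'
#' @param object A `jitai_compliance` report.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.jitai_compliance <- function(object, ...) {
  df <- object$by_kind |> filter(!is.na(.data$rate))
  ggplot(df, aes(x = .data$kind, y = .data$rate, fill = .data$origin)) +
    geom_col(position = "dodge") +
    scale_y_continuous(labels = function(x) paste0(100 * x, "%"),
                       limits = c(0, 1)) +
    labs(x = NULL, y = "Completion rate", fill = "Origin",
         title = "EMA completion by assessment kind") +
    theme_minimal()
}

#' Plot an abstinence report
#'
#' Point-prevalence abstinence proportion by visit, over the full enrolled
#' cohort.
#'
#' @param object A `jitai_abstinence` report.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.jitai_abstinence <- function(object, ...) {
  df <- object$by_visit |>
    mutate(visit = factor(.data$visit, levels = VISIT_LEVELS))
  ggplot(df, aes(x = .data$visit, y = .data$proportion, group = 1)) +
    geom_line() +
    geom_point() +
    scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    labs(x = "Visit", y = "Point-prevalence abstinence",
         title = "CO-verified 7-day point-prevalence abstinence") +
    theme_minimal()
}

#' Plot a feature-use report
#'
#' Median tips viewed per occasion by on-demand tip category.
#'
#' @param object A `jitai_feature_use` report.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.jitai_feature_use <- function(object, ...) {
  df <- object$by_category |> filter(!is.na(.data$intensity_median))
  ggplot(df, aes(x = .data$category, y = .data$intensity_median,
                 fill = .data$kind)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = "Median tips viewed per occasion", fill = NULL,
         title = "On-demand tip viewing intensity") +
    theme_minimal()
}

#' Plot delivered message levels over the study period
#'
#' Daily counts of delivered messages by level, pooled over participants —
#' a quick view of how the engine escalates after the quit date.
#'
#' @param messages A message tibble from [run_engine()].
#' @param participants The matching [participants()] tibble.
#' @return A ggplot.
#' @export
plot_message_levels <- function(messages, participants) {
  df <- messages |>
    left_join(
      participants |> select("participant_id", "enrollment_date", "wake_time"),
      by = "participant_id"
    )
  df$day <- mapply(
    function(at, enr, wt) study_day(as.POSIXct(at, tz = JITAI_TZ,
                                               origin = "1970-01-01"), enr, wt),
    as.numeric(df$at), as.list(as.Date(df$enrollment_date)), df$wake_time
  )
  ggplot(df, aes(x = .data$day, fill = .data$level)) +
    geom_bar() +
    labs(x = "Study day (wake-anchored)", y = "Messages delivered",
         fill = "Level", title = "Automated message levels by study day") +
    theme_minimal()
}
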