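#' Study configuration
#'
#' Bundles every protocol constant of the 3-week EMA intervention in one
#' validated object: 1 prequit week + 2 postquit weeks; one daily diary 30
#' minutes after waking plus 4 random prompts per day (5 prompted EMAs/day);
#' a 60-second prompt window; event-contingent follow-ups 15 minutes after a
#' sampled pre-cigarette assessment or an "About to Slip" report; at most 2
#' sampled smoking occasions per day; Level-2 escalation when the daily-diary
#' smoking likelihood is strictly above 25%; expired-CO abstinence cutoffs of
#' 8 ppm at follow-up visits and 10 ppm on the quit date (strictly below);
#' and compensation tiers of USD 40 / 80 / 120 at completion fractions of
#' 0.50 / 0.75 / 0.90.
#'
#' @param ... Named overrides of any default field. Nested lists
#'   (`compensation_tiers`, `risk_estimator`) are replaced wholesale when
#'   supplied, except `risk_estimator`, which is merged element-wise.
#'
#' @section Fields:
#' \describe{
#'   \item{quit_datetime}{Optional study-wide quit timestamp string; usually
#'     `NA` because each participant's quit time is derived as
#'     enrollment + `prequit_days` at wake time.}
#'   \item{prequit_days, postquit_days}{EMA period structure (7 + 14 = 21).}
#'   \item{diary_offset_min}{Daily diary delay after waking (30).}
#'   \item{n_random_per_day}{Random prompts per day (4).}
#'   \item{min_gap_min}{Minimum spacing between random prompts (30).}
#'   \item{prompt_window_sec}{Audible/visual cue duration; responses initiated
#'     later are missed (60).}
#'   \item{postcig_delay_min, slip_followup_delay_min}{Follow-up delays (15).}
#'   \item{max_sampled_cigs_per_day}{Smoking-occasion sampling cap (2).}
#'   \item{p_sample}{Probability an under-cap smoking occasion is sampled (1).}
#'   \item{diary_risk_threshold_pct}{Diary likelihood must be strictly above
#'     this to escalate to Level 2 (25).}
#'   \item{co_cutoff_followup_ppm, co_cutoff_quitdate_ppm}{Expired-CO
#'     verification cutoffs, strict "below" (8; 10 on the quit date).}
#'   \item{item_scale_max, diary_scale_max}{Response scales: 0-10 items,
#'     0-100 diary likelihood. Declared here so alternative scales are a
#'     configuration change.}
#'   \item{min_waking_hours}{Floor on the waking-window duration (8).}
#'   \item{compensation_tiers}{Ordered list of `(min_fraction, usd)`; below
#'     the first bound the amount is 0.}
#'   \item{risk_estimator}{Pluggable lapse-risk stand-in: linear `weights`
#'     over urge, negative affect/stress, cigarette availability, low
#'     motivation (`scale_max - motivation_to_quit`) and `smoked_since_last`,
#'     an `intercept`, and a `threshold`; risk is "high" iff
#'     score > threshold. A placeholder contract, swappable without touching
#'     the decision engine.}
#'   \item{rng_seed}{Default seed for stochastic operations.}
#' }
#'
#' @return A `jitai_config` list.
#' @examples
#' cfg <- study_config()
#' cfg$n_random_per_day
#' study_config(n_random_per_day = 2)$n_random_per_day
#' @export
study_config <- function(...) {
  cfg <- jitai_default_config()
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown)) {
      abort(paste0("Unknown config field(s): ", paste(unknown, collapse = ", ")))
    }
    for (nm in names(overrides)) {
      if (nm == "risk_estimator") {
        cfg$risk_estimator <- modifyList(cfg$risk_estimator, overrides[[nm]])
      } else {
        cfg[[nm]] <- overrides[[nm]]
      }
    }
  }
  validate_config(cfg)
}

jitai_default_config <- function() {
  list(
    quit_datetime = NA_character_,
    prequit_days = 7L,
    postquit_days = 14L,
    diary_offset_min = 30,
    n_random_per_day = 4L,
    min_gap_min = 30,
    prompt_window_sec = 60,
    postcig_delay_min = 15,
    slip_followup_delay_min = 15,
    max_sampled_cigs_per_day = 2L,
    p_sample = 1.0,
    diary_risk_threshold_pct = 25,
    co_cutoff_followup_ppm = 8,
    co_cutoff_quitdate_ppm = 10,
    item_scale_max = 10L,
    diary_scale_max = 100L,
    min_waking_hours = 8,
    compensation_tiers = list(
      list(min_fraction = 0.50, usd = 40),
      list(min_fraction = 0.75, usd = 80),
      list(min_fraction = 0.90, usd = 120)
    ),
    risk_estimator = list(
      intercept = -6,
      threshold = 0,
      weights = list(
        urge = 0.35,
        negative_affect_stress = 0.35,
        cigarette_availability = 0.15,
        low_motivation = 0.15,
        smoked_since_last = 1.0
      )
    ),
    rng_seed = 1L
  )
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  num_pos <- c(
    "diary_offset_min", "prompt_window_sec", "postcig_delay_min",
    "slip_followup_delay_min", "min_gap_min", "min_waking_hours"
  )
  for (nm in num_pos) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] <= 0) {
      abort(paste0("Config field `", nm, "` must be a positive number."))
    }
  }
  num_nonneg <- c(
    "diary_risk_threshold_pct", "co_cutoff_followup_ppm",
    "co_cutoff_quitdate_ppm", "n_random_per_day", "max_sampled_cigs_per_day"
  )
  for (nm in num_nonneg) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1 || cfg[[nm]] < 0) {
      abort(paste0("Config field `", nm, "` must be a nonnegative number."))
    }
  }
  if (cfg$prequit_days < 0 || cfg$postquit_days < 0 ||
      cfg$prequit_days + cfg$postquit_days < 1) {
    abort("Config fields `prequit_days` + `postquit_days` must span >= 1 day.")
  }
  if (cfg$p_sample < 0 || cfg$p_sample > 1) {
    abort("Config field `p_sample` must lie in [0, 1].")
  }
  tiers <- cfg$compensation_tiers
  bounds <- vapply(tiers, function(t) as.numeric(t$min_fraction), numeric(1))
  amounts <- vapply(tiers, function(t) as.numeric(t$usd), numeric(1))
  if (any(bounds < 0) || any(bounds > 1) || any(diff(bounds) <= 0)) {
    abort(paste0(
      "Config field `compensation_tiers`: tier bounds must be strictly ",
      "increasing within [0, 1], got (", paste(bounds, collapse = ", "), ")."
    ))
  }
  if (any(diff(amounts) < 0)) {
    abort("Config field `compensation_tiers`: amounts must be nondecreasing.")
  }
  re <- cfg$risk_estimator
  if (!is.numeric(re$intercept) || !is.numeric(re$threshold) ||
      !is.finite(re$threshold)) {
    abort("Config field `risk_estimator` needs finite `intercept` and `threshold`.")
  }
  structure(cfg, class = c("jitai_config", "list"))
}

#' Read a study configuration file
#'
#' Reads a YAML (or JSON, which YAML subsumes) configuration and fills every
#' absent key with the protocol default, so an empty file yields the default
#' configuration.
#'
#' @param path Path to a YAML/JSON config file.
#' @return A validated `jitai_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) abort(paste0("Could not parse config file: ", conditionMessage(e)))
  )
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) abort("Config file must contain a mapping of fields.")
  do.call(study_config, raw)
}

#' Write a study configuration file
#'
#' @param config A `jitai_config`.
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "jitai_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @export
print.jitai_config <- function(x, ...) {
  cat("<jitai study configuration>\n")
  cat(sprintf(
    "  EMA period: %d prequit + %d postquit days; %d prompted EMAs/day\n",
    x$prequit_days, x$postquit_days, 1L + as.integer(x$n_random_per_day)
  ))
  cat(sprintf(
    "  Prompt window %gs; follow-ups at %g min; <=%d sampled cigarettes/day\n",
    x$prompt_window_sec, x$postcig_delay_min, as.integer(x$max_sampled_cigs_per_day)
  ))
  cat(sprintf(
    "  Diary escalation > %g%%; CO cutoffs < %g ppm (quit date < %g ppm)\n",
    x$diary_risk_threshold_pct, x$co_cutoff_followup_ppm, x$co_cutoff_quitdate_ppm
  ))
  invisible(x)
}
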