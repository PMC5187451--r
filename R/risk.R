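#' Estimate momentary lapse risk
#'
#' A pluggable stand-in for the published lapse-risk estimator the app
#' delegated to: a deterministic linear score over the current EMA responses,
#' \deqn{score = intercept + w_u\,urge + w_s\,stress + w_a\,avail +
#'   w_m\,(scale\_max - motivation) + w_l\,smoked,}
#' with risk classed "high" iff `score > threshold` (strict). Low motivation
#' enters as `scale_max - motivation_to_quit` so that every term is
#' high-is-risky, making the default score monotone nondecreasing in urge and
#' negative affect/stress. Swap the `spec` (weights, intercept, threshold) in
#' the study configuration to change the estimator without touching the
#' decision engine.
#'
#' @param items Data frame of item responses (`urge`,
#'   `negative_affect_stress`, `cigarette_availability`,
#'   `motivation_to_quit`, `smoked_since_last`); vectorised over rows.
#' @param spec Risk-estimator spec (`weights`, `intercept`, `threshold`);
#'   defaults to the one in [study_config()].
#' @param scale_max Top of the item scale (default 10).
#' @return A tibble with columns `score` and `high_risk`.
#' @examples
#' estimate_lapse_risk(tibble::tibble(
#'   urge = c(0, 10), negative_affect_stress = c(0, 10),
#'   cigarette_availability = c(0, 10), motivation_to_quit = c(10, 0),
#'   smoked_since_last = FALSE
#' ))
#' @export
estimate_lapse_risk <- function(items, spec = NULL, scale_max = 10) {
  spec <- spec %||% jitai_default_config()$risk_estimator
  w <- spec$weights
  needed <- c("urge", "negative_affect_stress", "cigarette_availability",
              "low_motivation", "smoked_since_last")
  missing_w <- setdiff(needed, names(w))
  if (length(missing_w)) {
    abort(paste0(
      "Risk-estimator spec missing weight(s): ",
      paste(missing_w, collapse = ", ")
    ))
  }
  smoked <- items$smoked_since_last
  smoked <- ifelse(is.na(smoked), 0, as.numeric(smoked))
  score <- spec$intercept +
    w$urge * items$urge +
    w$negative_affect_stress * items$negative_affect_stress +
    w$cigarette_availability * items$cigarette_availability +
    w$low_motivation * (scale_max - items$motivation_to_quit) +
    w$smoked_since_last * smoked
  tibble(score = score, high_risk = score > spec$threshold)
}
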