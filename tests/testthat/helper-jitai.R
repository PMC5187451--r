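# Shared fixtures and independent oracles used across the suite.

# Context-row builder with neutral defaults; override per test.
make_context <- function(phase = "postquit", ema_kind = "random",
                         urge = 1, negative_affect_stress = 1,
                         cigarette_availability = 1, motivation_to_quit = 9,
                         score = NA_real_, high_risk = FALSE,
                         smoked_today_or_yesterday = FALSE,
                         diary_likelihood_today_pct = NA_integer_,
                         lapsed_and_uninterested = FALSE,
                         new_lapse_event = FALSE) {
  pre <- phase == "prequit"
  if (any(pre)) {
    high_risk <- ifelse(pre, NA, high_risk)
    smoked_today_or_yesterday <- ifelse(pre, NA, smoked_today_or_yesterday)
    lapsed_and_uninterested <- ifelse(pre, NA, lapsed_and_uninterested)
    new_lapse_event <- ifelse(pre, NA, new_lapse_event)
  }
  tibble::tibble(
    phase = phase, ema_kind = ema_kind,
    urge = urge, negative_affect_stress = negative_affect_stress,
    cigarette_availability = cigarette_availability,
    motivation_to_quit = motivation_to_quit,
    score = score, high_risk = high_risk,
    smoked_today_or_yesterday = smoked_today_or_yesterday,
    diary_likelihood_today_pct = diary_likelihood_today_pct,
    lapsed_and_uninterested = lapsed_and_uninterested,
    new_lapse_event = new_lapse_event
  )
}

# Independent brute-force truth table for the level rules, written as plain
# nested conditionals straight from the rule statement (not sharing code with
# the engine).
oracle_level <- function(phase, high_risk, smoked, diary_pct, kind,
                         uninterested, new_lapse, threshold = 25) {
  if (phase == "prequit") return("L0")
  if (isTRUE(uninterested)) return("L0")
  if (isTRUE(new_lapse)) return("L3")
  if (isTRUE(high_risk)) return("L2")
  if (isTRUE(smoked)) return("L2")
  if (!is.na(diary_pct) && diary_pct > threshold) return("L2")
  if (kind == "urge") return("L2")
  if (kind == "about_to_slip") return("L2")
  if (kind == "already_slipped") return("L2")
  "L1"
}

# Independent argmax-with-priority oracle for trigger selection: walk the
# stated preference order and keep the first trigger attaining the maximum.
oracle_trigger <- function(stress, urge, avail, motivation, scale_max = 10) {
  vals <- c(stress_affect = stress, urge = urge, availability = avail,
            motivation = scale_max - motivation)
  best <- names(vals)[1]
  for (nm in names(vals)) {
    if (vals[[nm]] > vals[[best]]) best <- nm
  }
  best
}

# Minimal message bank built in code (no file), complete for the engine.
tiny_bank <- function(n_l0 = 10, n_per_slot = 3) {
  rows <- list(
    tibble::tibble(level = "L0", trigger_or_category = "none",
                   message_id = sprintf("l0-%02d", seq_len(n_l0)),
                   text = sprintf("prequit message %d", seq_len(n_l0)))
  )
  slots <- list(
    c("L1", "none"), c("L2", "stress_affect"), c("L2", "urge"),
    c("L2", "availability"), c("L2", "motivation"), c("L3", "none")
  )
  for (s in slots) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      level = s[1], trigger_or_category = s[2],
      message_id = sprintf("%s-%s-%02d", tolower(s[1]), substr(s[2], 1, 2),
                           seq_len(n_per_slot)),
      text = sprintf("%s/%s message %d", s[1], s[2], seq_len(n_per_slot))
    )
  }
  for (cat in c("general_advice", "benefits", "coping_urges", "coping_stress",
                "coping_mood")) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      level = "quit_tips", trigger_or_category = cat,
      message_id = paste0("qt-", cat), text = paste("tip", cat)
    )
  }
  for (cat in c("varenicline", "patch", "gum", "bupropion")) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      level = "medication_tips", trigger_or_category = cat,
      message_id = paste0("mt-", cat), text = paste("tip", cat)
    )
  }
  jitai:::validate_message_bank(dplyr::bind_rows(rows))
}

ts <- function(x) as.POSIXct(x, tz = "UTC")
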