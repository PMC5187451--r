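test_that("level classification follows the stated precedence on key cases", {
  cfg <- study_config()
  expect_equal(classify_level(make_context(phase = "prequit"), cfg), "L0")
  expect_equal(
    classify_level(make_context(diary_likelihood_today_pct = 30L), cfg),
    "L2"
  )
  expect_equal(classify_level(make_context(), cfg), "L1")
  expect_equal(
    classify_level(make_context(lapsed_and_uninterested = TRUE,
                                smoked_today_or_yesterday = TRUE), cfg),
    "L0"
  )
  expect_equal(
    classify_level(make_context(new_lapse_event = TRUE,
                                ema_kind = "already_slipped",
                                smoked_today_or_yesterday = TRUE), cfg),
    "L3"
  )
  for (kind in c("urge", "about_to_slip", "already_slipped")) {
    expect_equal(classify_level(make_context(ema_kind = kind), cfg), "L2")
  }
  expect_error(
    classify_level(tibble::tibble(
      phase = "prequit", ema_kind = "random", high_risk = TRUE,
      smoked_today_or_yesterday = FALSE, diary_likelihood_today_pct = NA,
      lapsed_and_uninterested = FALSE, new_lapse_event = FALSE
    ), cfg),
    "Prequit context"
  )
})

test_that("classification matches the brute-force truth table exhaustively", {
  cfg <- study_config()
  combos <- tidyr::expand_grid(
    phase = c("prequit", "postquit"),
    high_risk = c(FALSE, TRUE),
    smoked = c(FALSE, TRUE),
    diary_pct = c(NA_integer_, 0L, 25L, 26L, 100L),
    kind = c("daily_diary", "random", "urge", "about_to_slip",
             "already_slipped", "slip_followup", "postcig"),
    uninterested = c(FALSE, TRUE),
    new_lapse = c(FALSE, TRUE)
  )
  # prequit contexts cannot carry postquit-only flags
  combos <- combos[combos$phase == "postquit" |
                     (!combos$high_risk & !combos$smoked &
                        !combos$uninterested & !combos$new_lapse), ]
  got <- classify_level(
    make_context(
      phase = combos$phase, ema_kind = combos$kind,
      high_risk = combos$high_risk,
      smoked_today_or_yesterday = combos$smoked,
      diary_likelihood_today_pct = combos$diary_pct,
      lapsed_and_uninterested = combos$uninterested,
      new_lapse_event = combos$new_lapse
    )[c("phase", "ema_kind", "high_risk", "smoked_today_or_yesterday",
        "diary_likelihood_today_pct", "lapsed_and_uninterested",
        "new_lapse_event")],
    cfg
  )
  want <- mapply(
    oracle_level, combos$phase, combos$high_risk, combos$smoked,
    combos$diary_pct, combos$kind, combos$uninterested, combos$new_lapse
  )
  expect_equal(got, unname(want))
})

test_that("trigger selection is argmax with the stated tie-break priority", {
  # tie between stress and urge goes to stress/affect
  expect_equal(
    select_trigger(tibble::tibble(
      urge = 4, negative_affect_stress = 4, cigarette_availability = 1,
      motivation_to_quit = 10
    )),
    "stress_affect"
  )
  # unique maximum wins
  expect_equal(
    select_trigger(tibble::tibble(
      urge = 9, negative_affect_stress = 5, cigarette_availability = 3,
      motivation_to_quit = 5
    )),
    "urge"
  )
  # four-way tie resolves to the first in the preference order
  expect_equal(
    select_trigger(tibble::tibble(
      urge = 6, negative_affect_stress = 6, cigarette_availability = 6,
      motivation_to_quit = 4
    )),
    "stress_affect"
  )
})

test_that("trigger selection matches the oracle over a dense grid", {
  grid <- tidyr::expand_grid(s = seq(0, 10, 2), u = seq(0, 10, 2),
                             a = seq(0, 10, 2), m = seq(0, 10, 2))
  got <- select_trigger(tibble::tibble(
    urge = grid$u, negative_affect_stress = grid$s,
    cigarette_availability = grid$a, motivation_to_quit = grid$m
  ))
  want <- mapply(oracle_trigger, grid$s, grid$u, grid$a, grid$m)
  expect_equal(got, unname(want))
})

test_that("message delivery follows bank order and avoids immediate repeats", {
  bank <- tiny_bank(n_l0 = 10, n_per_slot = 3)
  state <- message_state()
  ids <- character(7)
  for (i in 1:7) {
    res <- next_message("L0", "none", bank, state, participant_id = "P1",
                        at = ts("2015-01-02 09:00:00"))
    ids[i] <- res$event$message_id
    state <- res$state
  }
  expect_equal(ids, sprintf("l0-%02d", 1:7))  # predetermined order

  state <- message_state()
  got <- character(4)
  for (i in 1:4) {
    res <- next_message("L2", "urge", bank, state, participant_id = "P1",
                        at = ts("2015-01-12 09:00:00"))
    got[i] <- res$event$message_id
    state <- res$state
  }
  expect_true(all(got[-1] != got[-4]))  # no two consecutive identical ids

  one <- tiny_bank(n_l0 = 1, n_per_slot = 1)
  state <- message_state()
  same <- character(3)
  for (i in 1:3) {
    res <- next_message("L3", "none", one, state)
    same[i] <- res$event$message_id
    state <- res$state
  }
  expect_equal(unique(same), same[1])  # single-entry slot repeats

  expect_error(next_message("L2", "none", bank, message_state()), "trigger")
})

test_that("the prequit countdown message states the days remaining", {
  quit_dt <- ts("2015-01-08 08:00:00")
  expect_match(countdown_message(ts("2015-01-03 08:00:00"), quit_dt), "5 DAYS")
  expect_match(countdown_message(ts("2015-01-07 09:00:00"), quit_dt), "1 DAY")
  expect_no_match(countdown_message(ts("2015-01-07 09:00:00"), quit_dt),
                  "1 DAYS")
  expect_error(countdown_message(ts("2015-01-08 08:00:00"), quit_dt),
               "prequit")
})

test_that("on-demand use is logged with intensity; payment view reports compensation", {
  log <- empty_event_log()
  log <- record_on_demand(log, "P1", "quit_tips", ts("2015-01-10 11:00:00"),
                          category = "coping_urges", n_tips_viewed = 16)
  expect_equal(log$n_tips_viewed[1], 16L)
  expect_equal(log$category[1], "coping_urges")

  log <- record_on_demand(log, "P1", "medication_tips",
                          ts("2015-01-10 12:00:00"),
                          category = "gum", n_tips_viewed = 4)
  expect_equal(log$n_tips_viewed[2], 4L)

  log <- record_on_demand(log, "P1", "phone_counselor",
                          ts("2015-01-10 13:00:00"))
  expect_equal(sum(log$kind == "phone_counselor"), 1)

  expect_error(
    record_on_demand(log, "P1", "quit_tips", ts("2015-01-10 14:00:00"),
                     category = "coping_rain"),
    "Unknown quit_tips category"
  )

  # payment view computes the up-to-the-moment compensation: 9/10 -> top tier
  for (i in 1:10) {
    log <- dplyr::bind_rows(log, ema_record(
      "P1", "random", "prompted",
      status = if (i <= 9) "completed" else "missed",
      scheduled_at = sprintf("2015-01-1%d 10:00:00", i %% 10),
      presented_at = sprintf("2015-01-1%d 10:00:00", i %% 10),
      completed_at = if (i <= 9) sprintf("2015-01-1%d 10:02:00", i %% 10) else NA,
      latency_sec = if (i <= 9) 5 else NA_real_,
      urge = if (i <= 9) 1L else NA_integer_,
      ema_id = paste0("e", i)
    ))
  }
  log <- record_on_demand(log, "P1", "payment_view", ts("2015-01-20 09:00:00"))
  expect_equal(attr(log, "compensation"), 120)
})

test_that("replaying a log yields one message per completed EMA and prequit purity", {
  co <- simulate_cohort(behavior_params(n_participants = 6, seed = 21))
  msgs <- run_engine(co$events, co$participants, tiny_bank())
  completed <- co$events[co$events$record_type == "ema" &
                           co$events$status == "completed", ]
  expect_equal(nrow(msgs), nrow(completed))
  expect_setequal(msgs$source_ema_id, completed$ema_id)

  # no tailored (L1-L3) message ever carries a prequit timestamp
  quit_by_p <- stats::setNames(co$participants$quit_datetime,
                               co$participants$participant_id)
  prequit_msg <- msgs$at < quit_by_p[msgs$participant_id]
  expect_true(all(msgs$level[prequit_msg] == "L0"))
  # L2 iff a trigger is attached
  expect_equal(msgs$trigger != "none", msgs$level == "L2")
})

test_that("lapse bookkeeping: first new-lapse EMA is L3, later ones L2, uninterested L0", {
  cfg <- study_config()
  p <- participants("P1")
  mk <- function(kind, t, ema_id, smoked = NA, interested = NA, urge = 1L) {
    ema_record(
      "P1", kind,
      origin = if (kind %in% c("random", "daily_diary")) "prompted" else "self_initiated",
      status = "completed",
      scheduled_at = if (kind %in% c("random", "daily_diary")) t else NA,
      presented_at = t, completed_at = t, latency_sec = NA_real_,
      urge = urge, negative_affect_stress = 1L, cigarette_availability = 1L,
      motivation_to_quit = 9L, smoked_since_last = smoked,
      still_interested_in_quitting = interested, ema_id = ema_id
    )
  }
  log <- dplyr::bind_rows(
    mk("random", "2015-01-10 10:00:00", "e1", smoked = FALSE),
    mk("already_slipped", "2015-01-10 12:00:00", "e2", smoked = TRUE,
       interested = TRUE),
    mk("random", "2015-01-10 15:00:00", "e3", smoked = FALSE),
    mk("random", "2015-01-11 15:00:00", "e4", smoked = FALSE),
    # two clear days later: day 13 has no lapse on record for today/yesterday
    mk("random", "2015-01-13 10:00:00", "e5", smoked = FALSE),
    mk("already_slipped", "2015-01-13 12:00:00", "e6", smoked = TRUE,
       interested = FALSE)
  )
  ctx <- derive_contexts(log, p, cfg)
  lv <- classify_level(ctx, cfg)
  names(lv) <- ctx$ema_id
  expect_equal(unname(lv["e1"]), "L1")
  expect_equal(unname(lv["e2"]), "L3")  # first EMA recording the new lapse
  expect_equal(unname(lv["e3"]), "L2")  # smoked today
  expect_equal(unname(lv["e4"]), "L2")  # smoked yesterday
  expect_equal(unname(lv["e5"]), "L1")  # lapse aged out
  expect_equal(unname(lv["e6"]), "L0")  # lapsed and no longer interested
})
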