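test_that("every participant is prompted 105 times over the 21-day period", {
  for (seed in c(5, 17)) {
    co <- simulate_cohort(behavior_params(n_participants = 3, seed = seed))
    prompted <- co$events |>
      dplyr::filter(record_type == "ema", origin == "prompted") |>
      dplyr::count(participant_id)
    expect_equal(prompted$n, rep(105L, 3))  # 5/day x 21 days
  }
})

test_that("perfect responders with no self-initiated events complete all 105", {
  co <- simulate_cohort(behavior_params(
    n_participants = 2, p_respond = 1, self_initiated_rate = 0, seed = 2
  ))
  ema <- co$events[co$events$record_type == "ema", ]
  expect_equal(nrow(ema), 2 * 105)
  expect_true(all(ema$status == "completed"))
  msgs <- run_engine(co$events, co$participants, tiny_bank())
  expect_equal(nrow(msgs), 2 * 105)  # one message per completed EMA

  none <- simulate_cohort(behavior_params(
    n_participants = 1, p_respond = 0, self_initiated_rate = 0, seed = 3
  ))
  expect_equal(sum(none$events$status == "completed", na.rm = TRUE), 0)
})

test_that("simulation is reproducible: same seed gives byte-identical logs", {
  params <- behavior_params(n_participants = 2, seed = 31)
  f1 <- withr::local_tempfile(fileext = ".jsonl")
  f2 <- withr::local_tempfile(fileext = ".jsonl")
  write_event_log(simulate_cohort(params)$events, f1)
  write_event_log(simulate_cohort(params)$events, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("simulated logs satisfy the event-log and scheduler invariants", {
  co <- simulate_cohort(behavior_params(n_participants = 6, seed = 41))
  expect_silent(validate_events(co$events))
  ema <- co$events[co$events$record_type == "ema", ]
  prompted <- ema[ema$origin == "prompted", ]
  prompted <- dplyr::left_join(prompted, co$participants, by = "participant_id")
  # per participant-day: exactly 1 diary + 4 random, inside the waking window
  # (prompts always fall within one calendar day, so the date is the day key)
  per_day <- prompted |>
    dplyr::mutate(day = as.Date(scheduled_at)) |>
    dplyr::count(participant_id, day, kind)
  expect_true(all(per_day$n[per_day$kind == "daily_diary"] == 1))
  expect_true(all(per_day$n[per_day$kind == "random"] == 4))
  tod <- (as.numeric(prompted$scheduled_at) %% 86400) / 3600
  wake_h <- jitai:::clock_to_sec(prompted$wake_time) / 3600
  sleep_h <- jitai:::clock_to_sec(prompted$sleep_time) / 3600
  expect_true(all(tod >= wake_h - 1e-9 & tod <= sleep_h + 1e-9))
  # sampling cap: never more than 2 completed precig assessments per day
  precig <- ema[ema$kind == "precig", ]
  if (nrow(precig)) {
    per <- precig |>
      dplyr::mutate(day = as.Date(presented_at)) |>
      dplyr::count(participant_id, day)
    expect_true(all(per$n <= 2))
  }
  # follow-ups trail their trigger by exactly 15 minutes and carry the window
  expect_true(all(ema$origin[ema$kind == "postcig"] == "system_followup"))
  expect_true(all(ema$latency_sec <= 60, na.rm = TRUE))
})

test_that("completion and self-initiation rates recover the calibrated defaults", {
  co <- simulate_cohort(behavior_params(seed = 7))
  rec <- recover_parameters(co)
  # truth 0.87; binomial sampling error at ~6,195 prompts is ~0.4 pp
  expect_gte(rec$p_respond$estimate, 0.84)
  expect_lte(rec$p_respond$estimate, 0.90)
  cr <- compliance_report(co$events)
  expect_lt(abs(cr$overall$completion_rate - 0.87), 0.03)
  expect_lt(abs(cr$overall$mean_self_initiated - 15.5), 2)

  ideal <- simulate_cohort(behavior_params(
    n_participants = 2, p_respond = 1, seed = 9
  ))
  expect_equal(recover_parameters(ideal)$p_respond$estimate, 1)
})

test_that("hazard coefficient recovery is flagged when no lapses occur", {
  co <- simulate_cohort(behavior_params(
    n_participants = 2, seed = 13,
    lapse_hazard = list(intercept = -30)
  ))
  expect_warning(rec <- recover_parameters(co), "No lapses")
  expect_true(rec$hazard_skipped)
  expect_equal(nrow(tidy(rec)), 1)  # only p_respond recoverable
})

test_that("simulated visit tables respect the missed-visit and CO conventions", {
  co <- simulate_cohort(behavior_params(n_participants = 20, seed = 23))
  v <- co$visits
  expect_equal(nrow(v), 20 * 6)
  missed <- v[!v$attended, ]
  expect_true(all(is.na(missed$self_report_abstinent)))
  expect_true(all(is.na(missed$co_ppm)))
  expect_true(all(v$co_ppm >= 0, na.rm = TRUE))
  # abstinent implies attended, for every participant-visit
  v$abstinent <- classify_abstinence(v)
  expect_true(all(v$attended[v$abstinent]))
})
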