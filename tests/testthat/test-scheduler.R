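test_that("a default day yields 5 prompts: diary at wake+30 and 4 spaced random", {
  p <- participants("P001", wake_time = "08:00", sleep_time = "22:00")
  sched <- build_day_schedule(p, "2015-01-03", seed = 1)
  expect_equal(nrow(sched), 5)
  expect_equal(sum(sched$kind == "daily_diary"), 1)
  expect_equal(sum(sched$kind == "random"), 4)
  expect_equal(sched$scheduled_at[sched$kind == "daily_diary"],
               ts("2015-01-03 08:30:00"))
  expect_true(all(sched$scheduled_at >= ts("2015-01-03 08:00:00")))
  expect_true(all(sched$scheduled_at <= ts("2015-01-03 22:00:00")))
  gaps <- diff(sort(as.numeric(sched$scheduled_at)))
  expect_true(all(gaps >= 30 * 60))
})

test_that("schedule invariants hold across random windows and seeds", {
  wakes <- c("06:00", "07:30", "09:00")
  sleeps <- c("20:00", "22:30", "23:00")
  for (i in seq_along(wakes)) {
    p <- participants("P", wake_time = wakes[i], sleep_time = sleeps[i])
    for (seed in 1:15) {
      sched <- build_day_schedule(p, "2015-01-05", seed = seed)
      expect_equal(nrow(sched), 5)
      expect_true(all(sched$scheduled_at >= ts(paste("2015-01-05", wakes[i]))))
      expect_true(all(sched$scheduled_at <= ts(paste("2015-01-05", sleeps[i]))))
      expect_true(all(diff(sort(as.numeric(sched$scheduled_at))) >= 1800))
    }
  }
})

test_that("scheduling is deterministic given the seed and degenerate cases work", {
  p <- participants("P001")
  s1 <- build_day_schedule(p, "2015-01-04", seed = 42)
  s2 <- build_day_schedule(p, "2015-01-04", seed = 42)
  expect_identical(s1, s2)

  cfg0 <- study_config(n_random_per_day = 0L)
  solo <- build_day_schedule(p, "2015-01-04", cfg0, seed = 1)
  expect_equal(solo$kind, "daily_diary")
  expect_equal(solo$scheduled_at, ts("2015-01-04 08:30:00"))

  expect_error(build_day_schedule(p, "2014-12-31", seed = 1), "EMA period")
  tight <- participants("P2", wake_time = "08:00", sleep_time = "17:00")
  cfg_tight <- study_config(n_random_per_day = 10L, min_waking_hours = 6)
  expect_error(build_day_schedule(tight, "2015-01-02", cfg_tight, seed = 1),
               "min_gap")
})

test_that("the 60-second window decides completed vs missed", {
  p <- participants("P001")
  sched <- build_day_schedule(p, "2015-01-02", seed = 3)
  prompt <- sched[1, ]
  expect_equal(resolve_prompt(prompt, 59)$status, "completed")
  expect_equal(resolve_prompt(prompt, 61)$status, "missed")
  expect_equal(resolve_prompt(prompt, NA)$status, "missed")
  expect_error(resolve_prompt(prompt, -1), "nonnegative")
  done <- resolve_prompt(prompt, 30, duration_min = 5)
  expect_equal(as.numeric(done$completed_at - done$presented_at, units = "secs"),
               30 + 300)
})

test_that("at most 2 smoking occasions are sampled per day, 2 whenever >= 2 presses", {
  cfg <- study_config()
  p <- participants("P001")
  set.seed(99)
  for (rep in 1:400) {
    n_press <- sample(0:12, 1)
    state <- sampling_state()
    n_sampled <- 0L
    followup_gap_ok <- TRUE
    if (n_press > 0) {
      at <- sort(ts("2015-01-03 08:00:00") + runif(n_press, 0, 14 * 3600))
      for (t in as.list(at)) {
        res <- register_precig_event(p, t[[1]], state, cfg)
        state <- res$state
        if (res$sampled) {
          n_sampled <- n_sampled + 1L
          followup_gap_ok <- followup_gap_ok &&
            isTRUE(all.equal(as.numeric(res$followup_due - t[[1]],
                                        units = "mins"), 15))
        }
      }
    }
    expect_lte(n_sampled, 2)
    expect_equal(n_sampled, min(n_press, 2))  # always-sample rule, p_sample = 1
    expect_true(followup_gap_ok)
  }
})

test_that("postquit cigarette presses are rejected with an advisory", {
  p <- participants("P001")
  state <- sampling_state()
  expect_warning(
    res <- register_precig_event(p, ts("2015-01-15 12:00:00"), state),
    "postquit"
  )
  expect_false(res$sampled)
})

test_that("only About-to-Slip events queue a 15-minute follow-up", {
  state <- sampling_state()
  res <- register_slip_event("about_to_slip", ts("2015-01-15 14:00:00"), state)
  expect_equal(res$followup_due, ts("2015-01-15 14:15:00"))
  expect_equal(res$state$pending$kind, "slip_followup")

  for (kind in c("urge", "already_slipped")) {
    res2 <- register_slip_event(kind, ts("2015-01-15 14:00:00"), sampling_state())
    expect_null(res2$followup_due)
    expect_equal(nrow(res2$state$pending), 0)
  }
  p <- participants("P001")
  expect_error(
    register_slip_event("urge", ts("2015-01-03 14:00:00"), sampling_state(),
                        participant = p),
    "postquit"
  )
})
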