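test_that("compensation maps completion fractions to the printed tiers", {
  expect_equal(compute_compensation(94, 105), 80)   # 0.895 -> 75%-89% tier
  expect_equal(compute_compensation(95, 105), 120)  # 0.905 -> 90%+ tier
  expect_equal(compute_compensation(63, 105), 40)   # 0.60  -> 50%-74% tier
  expect_equal(compute_compensation(0, 105), 0)
  expect_equal(compute_compensation(c(52, 78, 94), 105), c(0, 40, 80))
  expect_error(compute_compensation(5, 0), "positive")
  expect_error(compute_compensation(-1, 10), "0, prompted")
})

test_that("compensation is monotone nondecreasing over the unit interval", {
  f <- seq(0, 1, by = 0.001)
  usd <- compute_compensation(round(f * 1000), 1000)
  expect_true(all(diff(usd) >= 0))
  # boundary fractions land in their half-open tiers
  expect_equal(compute_compensation(c(499, 500, 749, 750, 899, 900), 1000),
               c(0, 40, 40, 80, 80, 120))
})

test_that("compliance rates and completion times match hand computation", {
  mk <- function(i, status, kind = "random", minutes = 2) {
    ema_record(
      "P1", kind, "prompted", status,
      scheduled_at = sprintf("2015-01-02 %02d:00:00", 8 + i),
      presented_at = sprintf("2015-01-02 %02d:00:00", 8 + i),
      completed_at = if (status == "completed") {
        sprintf("2015-01-02 %02d:%02d:00", 8 + i, minutes)
      } else NA,
      latency_sec = if (status == "completed") 5 else NA_real_,
      urge = if (status == "completed") 2L else NA_integer_,
      ema_id = paste0("e", i)
    )
  }
  log <- dplyr::bind_rows(lapply(1:10, function(i) {
    mk(i, if (i <= 9) "completed" else "missed")
  }))
  rep <- compliance_report(log)
  expect_equal(rep$overall$completion_rate, 0.9)
  expect_equal(rep$by_participant$fraction, 0.9)
  expect_equal(rep$by_kind$mean_completion_min[rep$by_kind$kind == "random"], 2)

  selfi <- ema_record("P2", "urge", "self_initiated", "completed",
                      presented_at = "2015-01-12 10:00:00",
                      completed_at = "2015-01-12 10:02:00",
                      urge = 5L, ema_id = "s1")
  rep2 <- compliance_report(selfi)
  expect_true(is.na(rep2$overall$completion_rate))  # no prompted records
  expect_warning(compliance_report(empty_event_log()), "Empty")
})

test_that("feature-use frequency and intensity match hand computation", {
  log <- empty_event_log()
  for (i in 1:4) {
    log <- record_on_demand(log, "P1", "quit_tips",
                            ts(sprintf("2015-01-%02d 10:00:00", 9 + i)),
                            category = "coping_urges", n_tips_viewed = 18)
  }
  rep <- feature_use_report(log)
  cu <- rep$by_category[rep$by_category$category == "coping_urges", ]
  expect_equal(cu$n_users, 1L)
  expect_equal(cu$accesses_mean, 4)
  expect_equal(cu$intensity_median, 18)

  # two participants with 2 and 6 accesses: mean 4, median 4
  log2 <- empty_event_log()
  for (i in 1:2) log2 <- record_on_demand(log2, "A", "quit_tips",
                                          ts("2015-01-10 10:00:00"),
                                          "coping_stress", 5)
  for (i in 1:6) log2 <- record_on_demand(log2, "B", "quit_tips",
                                          ts("2015-01-11 10:00:00"),
                                          "coping_stress", 7)
  cs <- feature_use_report(log2)$by_category
  cs <- cs[cs$category == "coping_stress", ]
  expect_equal(cs$accesses_mean, 4)
  expect_equal(cs$accesses_median, 4)

  empty <- feature_use_report(empty_event_log())
  expect_true(all(empty$by_category$n_users == 0))

  presc <- tibble::tibble(participant_id = "P9", medication = "patch")
  log3 <- record_on_demand(empty_event_log(), "P9", "medication_tips",
                           ts("2015-01-10 10:00:00"), "gum", 4)
  np <- feature_use_report(log3, presc)$not_prescribed
  expect_equal(np$medication, "gum")
  expect_equal(np$n_viewers_not_prescribed, 1L)
})

test_that("abstinence requires attendance, self-report, and CO below the cutoff", {
  v <- function(visit, co, attended = TRUE, report = TRUE) {
    tibble::tibble(participant_id = "P1", visit = visit, attended = attended,
                   self_report_abstinent = if (attended) report else NA,
                   co_ppm = if (attended) co else NA_real_)
  }
  expect_true(classify_abstinence(v("wk4", 7)))
  expect_false(classify_abstinence(v("wk4", 8)))     # strict "below 8"
  expect_true(classify_abstinence(v("quit_date", 9)))  # 10 ppm on quit date
  expect_false(classify_abstinence(v("quit_date", 10)))
  expect_false(classify_abstinence(v("wk4", NA, attended = FALSE)))
  expect_false(classify_abstinence(v("wk4", 5, report = FALSE)))
  expect_error(classify_abstinence(tibble::tibble(
    participant_id = "P1", visit = "wk4", attended = TRUE,
    self_report_abstinent = TRUE, co_ppm = NA_real_
  )), "verification")
})

test_that("point prevalence uses the full cohort as denominator", {
  visits <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:59),
    visit = "wk12",
    attended = c(rep(TRUE, 46), rep(FALSE, 13)),
    self_report_abstinent = c(rep(TRUE, 12), rep(FALSE, 34), rep(NA, 13)),
    co_ppm = c(rep(4, 12), rep(20, 34), rep(NA, 13))
  )
  rep <- abstinence_report(visits)
  expect_equal(rep$by_visit$n_abstinent, 12L)
  expect_equal(rep$by_visit$proportion, 12 / 59, tolerance = 1e-12)

  all_missed <- tibble::tibble(
    participant_id = c("A", "B"), visit = "wk1", attended = FALSE,
    self_report_abstinent = NA, co_ppm = NA_real_
  )
  expect_equal(abstinence_report(all_missed)$by_visit$proportion, 0)

  dup <- dplyr::bind_rows(visits[1, ], visits[1, ])
  expect_error(abstinence_report(dup), "Duplicate")
})

test_that("reports are deterministic and plots build", {
  co <- simulate_cohort(behavior_params(n_participants = 4, seed = 77))
  r1 <- compliance_report(co$events)
  r2 <- compliance_report(co$events)
  expect_identical(r1, r2)
  expect_s3_class(autoplot(r1), "ggplot")
  expect_s3_class(autoplot(feature_use_report(co$events)), "ggplot")
  expect_s3_class(autoplot(abstinence_report(co$visits)), "ggplot")
  expect_s3_class(tidy(r1), "tbl_df")
  expect_s3_class(glance(r1), "tbl_df")
})
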