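# Synthetic-cohort generator. Latent urge / negative affect-stress /
# cigarette availability / motivation follow clipped AR(1) processes on an
# hourly grid over each waking window; prompt completion is independent
# Bernoulli per prompt; postquit lapses arise from a per-EMA-epoch logistic
# hazard in the current latent state, which gives the lapse-risk estimator a
# detectable signal by construction.

#' Behavioural simulation parameters
#'
#' Defaults are calibrated to the protocol's reported cohort: 59
#' participants, 87% per-prompt completion, 15.5 self-initiated assessments
#' per participant over the 3-week EMA period, 20.3 (SD 11.6) cigarettes/day
#' before quitting, visit attendance of 92/98/98/83/78% (quit date, weeks 1,
#' 2, 4, 12; week 3 is not reported and defaults to 90%), and baseline
#' expired CO of mean 18.6 (SD 13.0) ppm for smokers versus ~3 ppm for
#' abstainers.
#'
#' @param ... Named overrides of any default.
#' @section Fields:
#' \describe{
#'   \item{n_participants}{Cohort size (59).}
#'   \item{p_respond}{Per-prompt completion probability (0.87), applied
#'     independently to every prompted and system-follow-up assessment.}
#'   \item{self_initiated_rate}{Expected self-initiated assessments
#'     (cigarette + urge + slip) per participant over the EMA period (15.5).
#'     Prequit pre-cigarette assessments consume
#'     `prequit_days * E[min(N, cap)]` of this budget (N = daily cigarette
#'     count); the remainder is the postquit self-initiated Poisson mean.
#'     Setting 0 disables all participant-initiated events.}
#'   \item{ar}{AR(1) persistence `rho` (per hour) and innovation `sd` for
#'     the latent processes on the 0-10 item scale.}
#'   \item{latent_means}{Stationary means per construct, prequit and
#'     postquit.}
#'   \item{lapse_hazard}{Logistic per-epoch hazard coefficients on the
#'     latent state (low motivation = `scale_max - motivation`).}
#'   \item{feedback}{Coefficient through which delivered messages would
#'     reduce the hazard; 0 by default (no treatment effect simulated).}
#'   \item{time_of_day_adherence}{Amplitude of a sinusoidal time-of-day
#'     modifier on the completion logit; 0 (off) by default.}
#'   \item{cigs_per_day}{Prequit daily cigarette count distribution
#'     (negative binomial via mean/sd).}
#'   \item{visit_attendance}{Per-visit attendance probabilities.}
#'   \item{co}{Expired-CO distributions for abstainers vs smokers
#'     (truncated normal, ppm).}
#'   \item{weekly_relapse, weekly_recovery}{Weekly transition probabilities
#'     used to extend smoking status beyond the EMA period to the week-3/4/12
#'     visits.}
#'   \item{p_misreport}{Probability a currently smoking participant
#'     self-reports abstinence at a visit (CO verification catches these).}
#'   \item{on_demand}{On-demand feature-use generator: probability of being
#'     a user, per-category access means and tips-per-occasion medians.}
#'   \item{seed}{Cohort seed.}
#' }
#' @return A `jitai_behavior_params` list.
#' @export
behavior_params <- function(...) {
  p <- list(
    n_participants = 59L,
    p_respond = 0.87,
    self_initiated_rate = 15.5,
    ar = list(rho = 0.7, sd = 1.2),
    latent_means = list(
      prequit = c(urge = 6, negative_affect_stress = 5,
                  cigarette_availability = 8, motivation_to_quit = 7),
      postquit = c(urge = 4, negative_affect_stress = 5,
                   cigarette_availability = 4, motivation_to_quit = 7)
    ),
    lapse_hazard = list(
      intercept = -7, urge = 0.4, negative_affect_stress = 0.2,
      cigarette_availability = 0.15, low_motivation = 0.1
    ),
    feedback = 0,
    time_of_day_adherence = 0,
    cigs_per_day = list(mean = 20.3, sd = 11.6),
    visit_attendance = c(quit_date = 0.92, wk1 = 0.98, wk2 = 0.98,
                         wk3 = 0.90, wk4 = 0.83, wk12 = 0.78),
    co = list(abstinent_mean = 3, abstinent_sd = 2,
              smoker_mean = 18.6, smoker_sd = 13),
    weekly_relapse = 0.15,
    weekly_recovery = 0.10,
    p_misreport = 0.05,
    on_demand = list(
      p_user = 0.83,
      quit_tip_access_mean = c(general_advice = 1.4, benefits = 0.8,
                               coping_urges = 1.7, coping_stress = 1.2,
                               coping_mood = 1.3),
      quit_tip_intensity_median = c(general_advice = 15, benefits = 20,
                                    coping_urges = 16, coping_stress = 9,
                                    coping_mood = 11),
      med_tip_access_mean = c(varenicline = 1.6, patch = 1.4,
                              gum = 0.6, bupropion = 0.9),
      med_tip_intensity_median = c(varenicline = 10, patch = 11,
                                   gum = 4, bupropion = 4),
      p_counselor_user = 0.22,
      counselor_calls_mean = 0.4
    ),
    seed = 1L
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(p))
  if (length(unknown)) {
    abort(paste0("Unknown behaviour parameter(s): ",
                 paste(unknown, collapse = ", ")))
  }
  for (nm in names(overrides)) {
    p[[nm]] <- if (is.list(p[[nm]]) && is.list(overrides[[nm]])) {
      modifyList(p[[nm]], overrides[[nm]])
    } else {
      overrides[[nm]]
    }
  }
  stopifnot(
    p$p_respond >= 0, p$p_respond <= 1,
    p$ar$rho >= 0, p$ar$rho < 1,
    all(is.finite(unlist(p$lapse_hazard))),
    p$self_initiated_rate >= 0
  )
  structure(p, class = c("jitai_behavior_params", "list"))
}

# negative binomial size from mean/sd (var = mu + mu^2/size)
nb_size <- function(mean, sd) {
  v <- sd^2
  if (v <= mean) return(Inf)  # effectively Poisson
  mean^2 / (v - mean)
}

# E[min(N, cap)] for the daily cigarette count, cap = 2
expected_sampled_per_day <- function(params, config) {
  mu <- params$cigs_per_day$mean
  size <- nb_size(mu, params$cigs_per_day$sd)
  p0 <- dnbinom(0, mu = mu, size = size)
  p1 <- dnbinom(1, mu = mu, size = size)
  cap <- config$max_sampled_cigs_per_day
  if (cap != 2) {
    k <- 0:(cap - 1)
    pk <- dnbinom(k, mu = mu, size = size)
    return(sum(k * pk) + cap * (1 - sum(pk)))
  }
  (1 * p1 + 2 * (1 - p0 - p1)) * config$p_sample
}

# assessment durations in minutes, drawn per kind and phase
draw_duration <- function(kind, post, n = length(kind)) {
  mu <- ifelse(kind == "daily_diary", ifelse(post, 4.8, 6.1),
        ifelse(kind == "random", ifelse(post, 2.1, 2.3),
        ifelse(kind == "urge", 2.0,
        ifelse(kind == "already_slipped", 4.5, 2.5))))
  sg <- ifelse(kind == "daily_diary", ifelse(post, 1.5, 1.9),
        ifelse(kind == "random", ifelse(post, 0.9, 0.6),
        ifelse(kind == "urge", 0.9,
        ifelse(kind == "already_slipped", 1.5, 1.0))))
  pmax(0.5, rnorm(n, mu, sg))
}

#' Simulate one participant
#'
#' Generates the participant's full 21-day record: resolved prompt schedule
#' (completion independent Bernoulli `p_respond`), item responses read from
#' the latent AR(1) processes, prequit cigarette logging with the per-day
#' sampling cap and post-cigarette follow-ups, postquit lapses from the
#' logistic hazard at each prompted-EMA epoch, self-initiated urge/slip
#' assessments at the configured rate placed preferentially where latent
#' urge is high, on-demand feature use, and the follow-up visit table with
#' status-conditional expired CO. Fully reproducible given `seed`.
#'
#' @param params [behavior_params()].
#' @param config [study_config()].
#' @param participant One row of [participants()].
#' @param seed Integer seed for this participant's substream.
#' @return List with `events` (event-log tibble), `visits` (visit tibble)
#'   and `epochs` (per-epoch hazard covariates and lapse outcomes, the
#'   ground truth used by [recover_parameters()]).
#' @export
simulate_participant <- function(params, config, participant, seed) {
  local_seed(seed, {
    p <- participant
    n_days <- config$prequit_days + config$postquit_days
    dates <- p$enrollment_date + (seq_len(n_days) - 1L)
    quit_dt <- p$quit_datetime
    smax <- config$item_scale_max

    # --- latent AR(1) processes on an hourly waking-hours grid -------------
    wake_s <- clock_to_sec(p$wake_time)
    sleep_s <- clock_to_sec(p$sleep_time)
    hours <- seq(wake_s, sleep_s, by = 3600)
    grid <- as.POSIXct(
      rep(as.numeric(at_clock(dates, "00:00")), each = length(hours)) +
        rep(hours, times = n_days),
      tz = JITAI_TZ
    )
    ng <- length(grid)
    post_grid <- grid >= quit_dt
    constructs <- c("urge", "negative_affect_stress",
                    "cigarette_availability", "motivation_to_quit")
    mu <- vapply(constructs, function(nm) {
      ifelse(post_grid, params$latent_means$postquit[[nm]],
             params$latent_means$prequit[[nm]])
    }, numeric(ng))
    rho <- params$ar$rho
    innov_sd <- params$ar$sd
    z <- vapply(seq_along(constructs), function(j) {
      e <- rnorm(ng, 0, innov_sd)
      e[1] <- rnorm(1, 0, innov_sd / sqrt(1 - rho^2))
      as.numeric(stats::filter(e, rho, method = "recursive"))
    }, numeric(ng))
    latent <- pmin(pmax(mu + z, 0), smax)
    colnames(latent) <- constructs
    latent_at <- function(t) {
      idx <- pmax(1L, findInterval(as.numeric(t), as.numeric(grid)))
      latent[idx, , drop = FALSE]
    }

    # --- prompted schedule and resolution ----------------------------------
    sched <- bind_rows(lapply(seq_len(n_days), function(d) {
      build_day_schedule(p, dates[d], config)
    }))
    np <- nrow(sched)
    tod_mod <- if (params$time_of_day_adherence != 0) {
      hr <- (as.numeric(sched$scheduled_at) %% 86400) / 3600
      params$time_of_day_adherence * cos(2 * pi * (hr - 14) / 24)
    } else 0
    p_eff <- plogis(stats::qlogis(min(max(params$p_respond, 1e-12),
                                      1 - 1e-12)) + tod_mod)
    if (params$p_respond %in% c(0, 1)) p_eff <- params$p_respond
    done <- runif(np) < p_eff
    lat <- ifelse(done, runif(np, 2, config$prompt_window_sec - 5), NA_real_)
    post_p <- sched$scheduled_at >= quit_dt
    dur <- draw_duration(sched$kind, post_p)
    prompted <- tibble(
      record_type = "ema",
      ema_id = sprintf("%s-p%04d", p$participant_id, seq_len(np)),
      participant_id = p$participant_id,
      kind = sched$kind,
      origin = "prompted",
      scheduled_at = sched$scheduled_at,
      presented_at = sched$scheduled_at,
      completed_at = as.POSIXct(
        ifelse(done, as.numeric(sched$scheduled_at) + lat + dur * 60, NA),
        tz = JITAI_TZ
      ),
      status = ifelse(done, "completed", "missed"),
      latency_sec = lat
    )

    # --- prequit cigarette logging -----------------------------------------
    selfi <- list()
    followups <- list()
    cap <- config$max_sampled_cigs_per_day
    if (params$self_initiated_rate > 0 && config$prequit_days > 0) {
      size <- nb_size(params$cigs_per_day$mean, params$cigs_per_day$sd)
      for (d in seq_len(config$prequit_days)) {
        n_cig <- if (is.finite(size)) {
          rnbinom(1, mu = params$cigs_per_day$mean, size = size)
        } else {
          rpois(1, params$cigs_per_day$mean)
        }
        if (n_cig == 0) next
        press_at <- sort(at_clock(dates[d], p$wake_time) +
                           runif(n_cig) * (sleep_s - wake_s))
        n_sampled <- 0L
        for (t in as.list(press_at)) {
          if (n_sampled >= cap) break
          if (runif(1) > config$p_sample) next
          n_sampled <- n_sampled + 1L
          selfi[[length(selfi) + 1]] <- list(kind = "precig", at = t[[1]])
          followups[[length(followups) + 1]] <- list(
            kind = "postcig", due = t[[1]] + config$postcig_delay_min * 60
          )
        }
      }
    }

    # --- postquit lapse process at prompted-EMA epochs ---------------------
    epochs <- tibble(
      participant_id = character(), at = as.POSIXct(character(), tz = JITAI_TZ),
      urge = numeric(), negative_affect_stress = numeric(),
      cigarette_availability = numeric(), low_motivation = numeric(),
      lapse = integer()
    )
    lapse_times <- as.POSIXct(character(), tz = JITAI_TZ)
    ep_t <- sched$scheduled_at[post_p]
    if (length(ep_t)) {
      lx <- latent_at(ep_t)
      hz <- params$lapse_hazard
      lin <- hz$intercept + hz$urge * lx[, "urge"] +
        hz$negative_affect_stress * lx[, "negative_affect_stress"] +
        hz$cigarette_availability * lx[, "cigarette_availability"] +
        hz$low_motivation * (smax - lx[, "motivation_to_quit"])
      lapse <- as.integer(runif(length(ep_t)) < plogis(lin))
      epochs <- tibble(
        participant_id = p$participant_id, at = ep_t,
        urge = lx[, "urge"],
        negative_affect_stress = lx[, "negative_affect_stress"],
        cigarette_availability = lx[, "cigarette_availability"],
        low_motivation = smax - lx[, "motivation_to_quit"],
        lapse = lapse
      )
      lapse_times <- ep_t[lapse == 1L]
    }

    # --- postquit self-initiated assessments -------------------------------
    if (params$self_initiated_rate > 0 && config$postquit_days > 0) {
      rate_post <- max(
        0,
        params$self_initiated_rate -
          config$prequit_days * expected_sampled_per_day(params, config)
      )
      n_post <- rpois(1, rate_post)
      if (n_post > 0) {
        cand <- which(post_grid)
        wgt <- exp(0.5 * latent[cand, "urge"])
        pick <- sample(cand, n_post, replace = TRUE, prob = wgt)
        at_post <- grid[pick] + runif(n_post, 0, 3599)
        for (t in as.list(at_post)) {
          t <- t[[1]]
          recent_lapse <- any(lapse_times > t - 7200 & lapse_times <= t)
          kind <- if (recent_lapse && runif(1) < 0.7) {
            "already_slipped"
          } else if (runif(1) < 0.65) "urge" else "about_to_slip"
          selfi[[length(selfi) + 1]] <- list(kind = kind, at = t)
          if (kind == "about_to_slip") {
            followups[[length(followups) + 1]] <- list(
              kind = "slip_followup",
              due = t + config$slip_followup_delay_min * 60
            )
          }
        }
      }
    }

    self_tbl <- if (length(selfi)) {
      kinds <- vapply(selfi, `[[`, character(1), "kind")
      ats <- as.POSIXct(vapply(selfi, function(x) as.numeric(x$at), numeric(1)),
                        tz = JITAI_TZ)
      dur_s <- draw_duration(kinds, ats >= quit_dt)
      tibble(
        record_type = "ema",
        ema_id = sprintf("%s-s%04d", p$participant_id, seq_along(kinds)),
        participant_id = p$participant_id,
        kind = kinds,
        origin = "self_initiated",
        scheduled_at = as.POSIXct(NA_character_, tz = JITAI_TZ),
        presented_at = ats,
        completed_at = ats + dur_s * 60,
        status = "completed",
        latency_sec = NA_real_
      )
    } else NULL

    fup_tbl <- if (length(followups)) {
      kinds <- vapply(followups, `[[`, character(1), "kind")
      dues <- as.POSIXct(vapply(followups, function(x) as.numeric(x$due),
                                numeric(1)), tz = JITAI_TZ)
      nf <- length(kinds)
      # an About-to-Slip moment carries an elevated lapse hazard of its own;
      # a lapse drawn here is what the slip follow-up then confirms
      slip_i <- which(kinds == "slip_followup")
      if (length(slip_i)) {
        lx <- latent_at(dues[slip_i])
        hz <- params$lapse_hazard
        lin <- hz$intercept + hz$urge * lx[, "urge"] +
          hz$negative_affect_stress * lx[, "negative_affect_stress"] +
          hz$cigarette_availability * lx[, "cigarette_availability"] +
          hz$low_motivation * (smax - lx[, "motivation_to_quit"])
        slipped <- runif(length(slip_i)) < plogis(lin + 1.5)
        lapse_times <- sort(c(lapse_times, dues[slip_i][slipped] - 300))
      }
      done_f <- runif(nf) < params$p_respond
      lat_f <- ifelse(done_f, runif(nf, 2, config$prompt_window_sec - 5),
                      NA_real_)
      dur_f <- draw_duration(kinds, dues >= quit_dt)
      tibble(
        record_type = "ema",
        ema_id = sprintf("%s-f%04d", p$participant_id, seq_len(nf)),
        participant_id = p$participant_id,
        kind = kinds,
        origin = "system_followup",
        scheduled_at = dues,
        presented_at = dues,
        completed_at = as.POSIXct(
          ifelse(done_f, as.numeric(dues) + lat_f + dur_f * 60, NA),
          tz = JITAI_TZ
        ),
        status = ifelse(done_f, "completed", "missed"),
        latency_sec = lat_f
      )
    } else NULL

    ema <- bind_rows(prompted, self_tbl, fup_tbl)
    ema <- ema[order(event_time(ema)), ]

    # --- item responses for completed assessments --------------------------
    comp <- which(ema$status == "completed")
    for (nm in ITEM_COLS) ema[[nm]] <- NA
    if (length(comp)) {
      t_obs <- ema$presented_at[comp]
      lx <- latent_at(t_obs)
      obs <- pmin(pmax(round(lx + matrix(rnorm(length(lx), 0, 0.5),
                                         nrow = nrow(lx))), 0), smax)
      ema$urge[comp] <- as.integer(obs[, "urge"])
      ema$negative_affect_stress[comp] <-
        as.integer(obs[, "negative_affect_stress"])
      ema$cigarette_availability[comp] <-
        as.integer(obs[, "cigarette_availability"])
      ema$motivation_to_quit[comp] <- as.integer(obs[, "motivation_to_quit"])
      post_c <- t_obs >= quit_dt
      # smoked since the previous completed assessment (postquit: any lapse
      # in the interval; prequit: near-certain for current smokers)
      prev_t <- dplyr::lag(as.numeric(ema$presented_at[comp]))
      prev_t[is.na(prev_t)] <- -Inf
      n_lapse_before <- findInterval(as.numeric(t_obs), sort(as.numeric(lapse_times)))
      n_lapse_prev <- findInterval(prev_t, sort(as.numeric(lapse_times)))
      smoked_post <- n_lapse_before > n_lapse_prev
      smoked_pre <- ema$kind[comp] %in% c("precig", "postcig") |
        runif(length(comp)) < 0.95
      ema$smoked_since_last[comp] <- ifelse(post_c, smoked_post, smoked_pre)
      ema$smoked_since_last[comp][ema$kind[comp] == "already_slipped"] <- TRUE
      diary <- comp[ema$kind[comp] == "daily_diary"]
      if (length(diary)) {
        du <- latent_at(ema$presented_at[diary])[, "urge"]
        ema$diary_smoking_likelihood_pct[diary] <- as.integer(
          pmin(pmax(round(8 * du + rnorm(length(diary), 0, 8)), 0), 100)
        )
      }
      lapse_ctx <- comp[ema$kind[comp] %in% c("already_slipped", "slip_followup")]
      if (length(lapse_ctx)) {
        ema$still_interested_in_quitting[lapse_ctx] <-
          runif(length(lapse_ctx)) > 0.08
      }
      ema$alcohol_last_24h[comp] <- runif(length(comp)) < 0.2
    }
    ema <- coerce_event_types(ema)

    # --- on-demand feature use ---------------------------------------------
    od <- list()
    odp <- params$on_demand
    period_start <- at_clock(dates[1], p$wake_time)
    period_len <- n_days * 86400
    if (runif(1) < odp$p_user) {
      for (cat in names(odp$quit_tip_access_mean)) {
        n_acc <- rpois(1, odp$quit_tip_access_mean[[cat]])
        if (n_acc > 0) {
          od[[length(od) + 1]] <- tibble(
            kind = "quit_tips", category = cat,
            at = period_start + runif(n_acc) * period_len,
            n_tips = 1L + rpois(n_acc, odp$quit_tip_intensity_median[[cat]] - 1)
          )
        }
      }
      for (cat in names(odp$med_tip_access_mean)) {
        n_acc <- rpois(1, odp$med_tip_access_mean[[cat]])
        if (n_acc > 0) {
          od[[length(od) + 1]] <- tibble(
            kind = "medication_tips", category = cat,
            at = period_start + runif(n_acc) * period_len,
            n_tips = 1L + rpois(n_acc, odp$med_tip_intensity_median[[cat]] - 1)
          )
        }
      }
    }
    if (runif(1) < odp$p_counselor_user) {
      n_call <- 1L + rpois(1, odp$counselor_calls_mean)
      od[[length(od) + 1]] <- tibble(
        kind = "phone_counselor", category = NA_character_,
        at = period_start + runif(n_call) * period_len,
        n_tips = NA_integer_
      )
    }
    od_tbl <- if (length(od)) {
      odd <- bind_rows(od)
      tibble(
        record_type = "on_demand",
        ema_id = NA_character_,
        participant_id = p$participant_id,
        kind = odd$kind,
        origin = NA_character_,
        scheduled_at = as.POSIXct(NA_character_, tz = JITAI_TZ),
        presented_at = odd$at,
        completed_at = as.POSIXct(NA_character_, tz = JITAI_TZ),
        status = NA_character_,
        latency_sec = NA_real_,
        category = odd$category,
        n_tips_viewed = odd$n_tips
      )
    } else NULL

    events <- coerce_event_types(bind_rows(empty_event_log(), ema, od_tbl))
    events <- events[order(event_time(events)), ]

    # --- follow-up visits ---------------------------------------------------
    visit_day <- c(quit_date = config$prequit_days + 1L,
                   wk1 = config$prequit_days + 8L,
                   wk2 = config$prequit_days + 15L,
                   wk3 = config$prequit_days + 22L,
                   wk4 = config$prequit_days + 29L,
                   wk12 = config$prequit_days + 85L)
    end_day <- n_days
    lapse_day <- study_day(lapse_times, p$enrollment_date, p$wake_time)
    smoked_final_week <- any(lapse_day > end_day - 7)
    week_state <- logical(0)  # TRUE = smoking, weekly beyond the EMA period
    state <- smoked_final_week
    for (w in seq_len(10)) {  # up to week 12
      state <- if (state) runif(1) > params$weekly_recovery
               else runif(1) < params$weekly_relapse
      week_state[w] <- state
    }
    visits <- lapply(VISIT_LEVELS, function(v) {
      d <- visit_day[[v]]
      attended <- runif(1) < params$visit_attendance[[v]]
      if (d <= end_day + 1L) {
        window_lo <- if (v == "quit_date") config$prequit_days + 1L else d - 7L
        truth_smoking <- any(lapse_day >= window_lo & lapse_day < d + 1L)
      } else {
        w <- ceiling((d - end_day) / 7)
        truth_smoking <- week_state[min(w, length(week_state))]
      }
      if (!attended) {
        return(tibble(
          participant_id = p$participant_id, visit = v, attended = FALSE,
          self_report_abstinent = NA, co_ppm = NA_real_
        ))
      }
      self_report <- if (truth_smoking) runif(1) < params$p_misreport
                     else runif(1) < 0.98
      co <- if (truth_smoking) {
        max(1, rnorm(1, params$co$smoker_mean, params$co$smoker_sd))
      } else {
        max(0, rnorm(1, params$co$abstinent_mean, params$co$abstinent_sd))
      }
      tibble(
        participant_id = p$participant_id, visit = v, attended = TRUE,
        self_report_abstinent = self_report, co_ppm = round(co, 1)
      )
    })
    list(events = events, visits = bind_rows(visits), epochs = epochs)
  })
}

#' Simulate a study cohort
#'
#' Runs [simulate_participant()] for `n_participants` independent substreams
#' and concatenates the outputs, keeping the generating parameters attached
#' so recovery tests can compare estimates against truth. Waking windows are
#' drawn per participant (wake between 06:00 and 09:00, 14-16 waking hours).
#'
#' @param params [behavior_params()].
#' @param config [study_config()].
#' @return A `jitai_cohort` list: `events`, `visits`, `epochs`,
#'   `participants`, `params`, `config`.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(behavior_params(n_participants = 5, seed = 1))
#' compliance_report(cohort$events)$overall
#' }
#' @export
simulate_cohort <- function(params = behavior_params(),
                            config = study_config()) {
  n <- params$n_participants
  stopifnot(n >= 1)
  ppl <- local_seed(substream_seed(params$seed, 0), {
    wake_h <- 6 + floor(runif(n, 0, 7)) / 2        # 06:00 .. 09:00 by 30 min
    dur_h <- 14 + floor(runif(n, 0, 5)) / 2        # 14 .. 16 waking hours
    participants(
      id = sprintf("P%03d", seq_len(n)),
      wake_time = sprintf("%02d:%02d", floor(wake_h), (wake_h %% 1) * 60),
      sleep_time = sprintf("%02d:%02d", floor(wake_h + dur_h),
                           ((wake_h + dur_h) %% 1) * 60),
      enrollment_date = "2015-01-01",
      config = config
    )
  })
  sims <- lapply(seq_len(n), function(i) {
    simulate_participant(params, config, ppl[i, ],
                         seed = substream_seed(params$seed, i))
  })
  structure(
    list(
      events = bind_rows(lapply(sims, `[[`, "events")),
      visits = bind_rows(lapply(sims, `[[`, "visits")),
      epochs = bind_rows(lapply(sims, `[[`, "epochs")),
      participants = ppl,
      params = params,
      config = config
    ),
    class = "jitai_cohort"
  )
}

#' @export
print.jitai_cohort <- function(x, ...) {
  prompted <- x$events[x$events$record_type == "ema" &
                         !is.na(x$events$origin) &
                         x$events$origin == "prompted", ]
  cat(sprintf(
    "<jitai simulated cohort: %d participants, %d events (%d prompted EMAs, %.1f%% completed)>\n",
    nrow(x$participants), nrow(x$events), nrow(prompted),
    100 * mean(prompted$status == "completed")
  ))
  invisible(x)
}

#' Recover generating parameters from a simulated cohort
#'
#' Estimates the per-prompt completion probability as completed/prompted over
#' prompted-origin EMAs (with a binomial standard error), and the lapse-hazard
#' coefficients by maximum likelihood (logistic regression of the per-epoch
#' lapse outcomes on the latent covariates). With no lapses in the dataset
#' the coefficient recovery is flagged and skipped.
#'
#' @param cohort A [simulate_cohort()] result.
#' @return A `jitai_recovery` object; see [tidy.jitai_recovery()].
#' @export
recover_parameters <- function(cohort) {
  stopifnot(inherits(cohort, "jitai_cohort"))
  prompted <- cohort$events[cohort$events$record_type == "ema" &
                              !is.na(cohort$events$origin) &
                              cohort$events$origin == "prompted", ]
  n <- nrow(prompted)
  k <- sum(prompted$status == "completed")
  p_hat <- k / n
  p_se <- sqrt(p_hat * (1 - p_hat) / n)
  ep <- cohort$epochs
  hz <- cohort$params$lapse_hazard
  truth <- c("(Intercept)" = hz$intercept, urge = hz$urge,
             negative_affect_stress = hz$negative_affect_stress,
             cigarette_availability = hz$cigarette_availability,
             low_motivation = hz$low_motivation)
  hazard_skipped <- !nrow(ep) || sum(ep$lapse) == 0
  hazard <- NULL
  if (!hazard_skipped) {
    fit <- glm(
      lapse ~ urge + negative_affect_stress + cigarette_availability +
        low_motivation,
      family = binomial(), data = ep
    )
    sm <- summary(fit)$coefficients
    hazard <- tibble(
      term = rownames(sm),
      estimate = sm[, "Estimate"],
      std.error = sm[, "Std. Error"],
      truth = unname(truth[rownames(sm)])
    )
  } else if (nrow(ep)) {
    warn("No lapses in the simulated dataset; hazard recovery skipped.")
  }
  structure(
    list(
      p_respond = list(estimate = p_hat, se = p_se, n = n,
                       truth = cohort$params$p_respond),
      hazard = hazard,
      hazard_skipped = hazard_skipped,
      n_epochs = nrow(ep),
      n_lapses = if (nrow(ep)) sum(ep$lapse) else 0L
    ),
    class = "jitai_recovery"
  )
}

#' @export
print.jitai_recovery <- function(x, ...) {
  cat(sprintf(
    "<jitai parameter recovery> p_respond %.3f (SE %.4f, truth %.3f)\n",
    x$p_respond$estimate, x$p_respond$se, x$p_respond$truth
  ))
  if (!x$hazard_skipped) print(x$hazard) else cat("  hazard recovery skipped\n")
  invisible(x)
}

#' Tidy a parameter-recovery fit
#'
#' @param x A `jitai_recovery`.
#' @param ... Unused.
#' @return One row per recovered parameter: `term`, `estimate`, `std.error`,
#'   `truth`.
#' @export
tidy.jitai_recovery <- function(x, ...) {
  out <- tibble(
    term = "p_respond",
    estimate = x$p_respond$estimate,
    std.error = x$p_respond$se,
    truth = x$p_respond$truth
  )
  if (!x$hazard_skipped) out <- bind_rows(out, x$hazard)
  out
}

#' @rdname tidy.jitai_recovery
#' @export
glance.jitai_recovery <- function(x, ...) {
  tibble(
    n_prompted = x$p_respond$n,
    completion_rate = x$p_respond$estimate,
    n_epochs = x$n_epochs,
    n_lapses = x$n_lapses,
    hazard_recovered = !x$hazard_skipped
  )
}
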