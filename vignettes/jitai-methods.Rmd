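---
title: "Methods: the EMA scheduler, message-tailoring algorithm, and cohort simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the EMA scheduler, message-tailoring algorithm, and cohort simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jitai)
library(dplyr)
```

## The intervention model

`jitai` implements the decision core of a smartphone-delivered just-in-time
adaptive intervention (JITAI) for smoking cessation, built on ecological
momentary assessment (EMA). A participant enrolls, carries the phone for a
3-week EMA period (1 prequit week, 2 postquit weeks), and answers three kinds
of assessments:

* a **daily diary**, 30 minutes after waking;
* **random** assessments, 4 per day within the participant's waking hours;
* **event-contingent** assessments the participant initiates: logging a
  cigarette before smoking it (prequit), and urge / About-to-Slip /
  Already-Slipped reports (postquit).

Prompted assessments are cued for 60 seconds; if no response is initiated
within the window the assessment is missed, finally (no snooze). To cap
burden in heavy smokers, at most 2 logged smoking occasions per day receive
the full pre-cigarette assessment; each sampled occasion triggers a
post-cigarette follow-up 15 minutes later. An About-to-Slip report triggers a
follow-up 15 minutes later asking whether the participant actually smoked.

At the end of **every completed EMA** the engine delivers exactly one
automated message at one of four levels:

| Level | When | Content |
|---|---|---|
| L0 | prequit; or postquit after a lapse when the participant is no longer interested in quitting | untailored, delivered in a predetermined order |
| L1 | postquit, low imminent lapse risk | motivation, general cessation advice |
| L2 | postquit: high imminent risk, **or** smoked today/yesterday, **or** daily-diary smoking likelihood strictly above 25%, **or** any urge/slip assessment | coping with the *currently highest rated* lapse trigger |
| L3 | the first EMA recording a new lapse | encourage return to abstinence |

Level-2 tailoring compares four trigger intensities — negative affect/stress,
smoking urge, cigarette availability, and *low* motivation to quit (encoded
as `scale_max − motivation` so all four are high-is-bad) — and ties are
broken in exactly that preference order.

## Design choices where the protocol is open

Several details are not pinned down by the protocol; the package fixes them
once, as configuration defaults, and documents the choice here.

**Item scales.** Response scales for the EMA items are not specified.
We adopt 0–10 integer scales for urge, negative affect/stress, cigarette
availability and motivation, and 0–100 for the diary smoking-likelihood
percentage. The scales live in `study_config()` (`item_scale_max`,
`diary_scale_max`), so an alternative scale is a configuration change.

**Day boundary.** Timestamps are timezone-naive study-local times, and the
participant day runs from wake time to wake time, because the daily diary —
and therefore the behavioural day — is anchored to waking, not midnight.
"Smoked today or the day before" uses this boundary.

**Random-prompt placement.** The protocol says only "random ... during
waking hours". We partition the waking window into `n_random_per_day` equal
strata and draw uniformly within each, rejecting draws in which any pair of
prompts (diary included) is closer than `min_gap_min` (default 30 minutes).
Stratification spreads prompts across the day, which is standard
experience-sampling practice; the rejection step enforces spacing.

**Occasion sampling rule.** "Randomly sampled up to 2 occasions/day" does
not state a mechanism. The default samples every logged occasion while the
day is under the cap (`p_sample = 1`), the simplest rule satisfying the cap;
a probabilistic rule is available by setting `p_sample < 1`. The cap counts
completed pre-cigarette assessments, not button presses.

**The 60-second window vs completion times.** The cue window governs
whether a response is *initiated*; completing the items then takes minutes
(diaries ~5–6, random assessments ~2). Records therefore carry both an
initiation latency (`latency_sec`, must be within the window for completed
prompted records) and a `completed_at` timestamp minutes later, from which
the compliance report computes per-kind completion times.

**Lapse-risk estimator.** The production system used a published lapse-risk
estimator whose internals are out of scope here. The package ships a
*pluggable placeholder contract*: a linear score over urge, stress/affect,
availability, low motivation and recent smoking, with weights, intercept
(−6) and threshold (0) in `study_config()$risk_estimator`. The defaults are
chosen so that an all-zero response pattern is low risk and an all-extreme
pattern (urge = stress = availability = 10, motivation = 0) scores 4 > 0,
i.e. high risk, and the score is monotone in urge and stress. Swapping in a
different estimator is a configuration change; the decision engine only
consumes `score > threshold`.

**L2/L3 precedence after a lapse.** Already-Slipped assessments are listed
among the Level-2 deliveries, yet Level 3 follows a lapse. We resolve this
deterministically: the *first* completed EMA that records a new lapse (an
Already-Slipped report, or a slip follow-up confirming smoking, with no
lapse already on record for today/yesterday) receives L3; subsequent EMAs
while "smoked today or yesterday" holds receive L2. This honours both rules
with a fixed precedence, but the original app's behaviour may differ.

**Diary threshold context.** The >25% rule escalates on what the
participant "indicated on the daily diary that day": the context feature is
today's (wake-anchored) diary value, null if no diary was completed today,
rather than the last diary whenever it occurred.

## The synthetic cohort

`simulate_cohort()` generates event logs and visit tables with the
statistical structure the engine and metrics assume, so the whole pipeline
is exercisable without participant data. Defaults reproduce the study
conditions: 59 participants, 87% per-prompt completion, 15.5 self-initiated
assessments per participant, prequit consumption of 20.3 (SD 11.6)
cigarettes/day, visit attendance 92/98/98/83/78% (quit date, weeks 1, 2, 4,
12), and expired CO near 18.6 (SD 13) ppm for smokers versus ~3 ppm for
abstainers. Week-3 attendance is not reported; we use 0.90, between the
neighbouring visits.

The generative model, in brief:

* **Latent state.** Urge, negative affect/stress, cigarette availability
  and motivation follow independent AR(1) processes (persistence 0.7/hour,
  innovation SD 1.2) on an hourly grid over each waking window, clipped to
  the 0–10 scale, with mean shifts at the quit date (urge and availability
  drop). Observed item responses are the latent values at the assessment
  time plus small rounding noise.
* **Compliance.** Each prompted or follow-up assessment is completed
  independently with probability `p_respond` (0.87). A time-of-day modifier
  on the completion logit exists but defaults to off, since only marginal
  compliance is reported.
* **Lapses.** At every postquit prompted-EMA epoch a lapse occurs with
  probability `plogis(−7 + 0.4·urge + 0.2·stress + 0.15·avail +
  0.1·low-motivation)` evaluated at the latent state — a logistic hazard
  that gives the risk estimator a detectable signal by construction.
  About-to-Slip moments carry an elevated draw of the same hazard, which is
  what the slip follow-up then confirms.
* **Self-initiation.** The 15.5-per-participant budget is split
  analytically: prequit cigarette logging contributes
  `prequit_days · E[min(N, 2)]` assessments (N the negative-binomial daily
  cigarette count — ≈14 at the defaults), and the remainder (≈1.5) is the
  Poisson mean of postquit urge/slip reports, placed preferentially where
  latent urge is high. Already-Slipped reports follow recent (≤2 h) lapses.
* **Visits.** Smoking status beyond the EMA period evolves as a weekly
  two-state chain (relapse 0.15/week, recovery 0.10/week from the final-week
  state). Attended visits record a self-report (5% of smokers misreport
  abstinence — CO verification catches them) and a status-conditional CO
  reading.

What the simulator does **not** emulate: treatment effects (delivered
messages do not feed back into the hazard unless the `feedback` coefficient
is raised from 0), within-day compliance structure, weekends, measurement
reactivity, or the heavy-tailed on-demand "binge viewing" seen in real
usage. Passing calibration tests therefore shows the pipeline is correct
and internally consistent — not that the generative model is behaviourally
faithful.

## Numerical conventions

* Boundary conventions are strict where the protocol language is strict:
  diary escalation requires likelihood **>** 25; abstinence requires CO
  **<** 8 ppm (10 on the quit date); compensation tiers are half-open at
  0.50/0.75/0.90 on the real-valued completion fraction, so 94/105 (0.895)
  earns $80 and 95/105 (0.905) earns $120.
* A response initiated at exactly the 60-second cue boundary counts as
  completed.
* Scheduling retries stratified draws up to 1,000 times before concluding
  the waking window cannot host the requested prompts at the requested
  spacing; the error suggests reducing `min_gap_min`.
* All randomness flows through explicit seeds; per-participant substreams
  are derived from the cohort seed, so cohorts are reproducible and
  participants independent.

## Problem sizes used in validation

The packaged tests exercise single days and participants for exact checks;
calibration uses 59-participant cohorts (10 replicate seeds for the mean
completion rate) and one scaled-up 590-participant cohort for
hazard-coefficient recovery, sizes at which binomial/MLE sampling error is
small relative to the tolerances asserted. The acceptance script averages
the pooled completion rate over 20 cohort seeds.

## Worked example

```{r example, eval = FALSE}
cfg <- study_config()
cohort <- simulate_cohort(behavior_params(n_participants = 59, seed = 1), cfg)
messages <- run_engine(cohort$events, cohort$participants,
                       default_message_bank(), cfg)
compliance_report(cohort$events, messages)$overall
abstinence_report(cohort$visits, cfg)$by_visit
```

## Known limitations

* The lapse-risk placeholder is a contract, not a validated estimator;
  deployment would swap in a fitted model.
* The simulator's AR(1)-plus-logistic structure is the simplest model with
  the needed autocorrelation and signal; its parameters are surfaced in
  `behavior_params()` but have not been fitted to momentary data.
* The L2/L3 precedence after a lapse is one deterministic reading of an
  ambiguous rule pair.
* On-demand content is logged, not rendered; the quitline and staff-call
  buttons are stubs that record the access.
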