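# jitai

`jitai` is an R implementation of the decision core of a smartphone-delivered
**just-in-time adaptive intervention (JITAI) for smoking cessation** built on
ecological momentary assessment (EMA). It is aimed at mHealth methodologists
and intervention designers who want to specify, test and power this class of
intervention **without participant data**: every protocol rule is executable,
and a synthetic-cohort simulator generates event logs and visit tables with
the statistical structure the rules assume.

The package covers:

* **Prompt scheduling** — one daily diary 30 minutes after waking plus 4
  random prompts stratified across each participant's waking hours (5
  prompted EMAs/day for 21 days: 1 prequit week, 2 postquit weeks), a
  60-second answer window, event-contingent follow-ups 15 minutes after a
  sampled pre-cigarette assessment or an About-to-Slip report, and a cap of
  2 sampled smoking occasions per day.
* **The four-level tailored-message algorithm** — every completed EMA maps
  to exactly one message:

  L0 (prequit, predetermined order; also postquit after a lapse when no
  longer interested in quitting) → L1 (low imminent lapse risk) →
  L2 (high risk, smoked today/yesterday, diary smoking likelihood > 25%, or
  any urge/slip assessment — tailored to the highest rated lapse trigger,
  ties broken stress/affect ≻ urge ≻ availability ≻ motivation) →
  L3 (first EMA recording a new lapse).

  Imminent risk comes from a **pluggable linear lapse-risk score**
  (weights/intercept/threshold in the study configuration; high risk iff
  score > threshold).
* **On-demand content logging** — Quit Tips (5 categories), Medication Tips
  (4 medications), quitline/staff call stubs, and a payment view that
  computes up-to-the-moment compensation.
* **Feasibility metrics** — per-kind compliance and completion times,
  compensation tiers ($0/$40/$80/$120 at completion fractions
  0.50/0.75/0.90), on-demand frequency/intensity tables, and CO-verified
  7-day point-prevalence abstinence (self-report **and** expired CO
  strictly below 8 ppm — 10 ppm on the quit date; missed visit ⇒
  nonabstinent, denominators are the full enrolled cohort).
* **A behavioural cohort simulator** — latent AR(1)
  urge/stress/availability/motivation dynamics, Bernoulli(0.87) prompt
  compliance, a logistic per-epoch lapse hazard, self-initiated assessments
  at 15.5 per participant, and attendance/CO-realistic visit tables —
  plus `recover_parameters()` to check the generating values are
  recoverable from the simulated data.

See `vignettes/jitai-methods.Rmd` for the model, the design decisions and
their rationale.

## Worked example

```r
library(jitai)

cfg    <- study_config()                                   # all protocol constants
cohort <- simulate_cohort(behavior_params(n_participants = 59, seed = 1), cfg)
msgs   <- run_engine(cohort$events, cohort$participants,
                     default_message_bank(), cfg)

compliance_report(cohort$events, msgs)$overall
#>   n_prompted n_completed completion_rate completion_rate_all_origins
#> 1       6195        5404          0.8723                      0.8707
#>   mean_self_initiated mean_messages_per_participant
#> 1               15.92                         120.2

table(msgs$level)
#>   L0   L1   L2   L3
#> 3341 1061 2683    4

abstinence_report(cohort$visits, cfg)$by_visit |> head(2)
#>       visit n_abstinent n_enrolled proportion
#> 1 quit_date          46         59  0.7796610
#> 2       wk1          10         59  0.1694915

compute_compensation(c(95, 63), 105, cfg)
#> [1] 120  40
```

Reading the output: the 59 simulated participants were prompted 6,195 times
(105 each) and completed 87.2% — matching the calibrated per-prompt response
probability; each averaged 15.9 self-initiated assessments. Every one of the
5,404 + self-initiated/follow-up completed EMAs received exactly one message;
prequit EMAs are all L0, postquit EMAs split between low-risk L1 and
escalated L2, with the rare L3 marking a newly reported lapse. A participant
completing 95 of 105 prompts (90.5%) earns the top $120 tier; 63 of 105
(60%) earns $40. Abstinence proportions are emulated behaviour, not a
reproduction of any real cohort's outcomes.

A thin CLI over the same functions lives at `inst/cli/jitai.R`
(`simulate`, `run-engine`, `metrics`, `schedule` subcommands).

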