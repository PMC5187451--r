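# Default study configuration. Absent keys fall back to protocol defaults,
# so this file doubles as documentation of the schema.
prequit_days: 7
postquit_days: 14
diary_offset_min: 30
n_random_per_day: 4
min_gap_min: 30
prompt_window_sec: 60
postcig_delay_min: 15
slip_followup_delay_min: 15
max_sampled_cigs_per_day: 2
p_sample: 1.0
diary_risk_threshold_pct: 25
co_cutoff_followup_ppm: 8
co_cutoff_quitdate_ppm: 10
item_scale_max: 10
diary_scale_max: 100
min_waking_hours: 8
compensation_tiers:
- min_fraction: 0.50
  usd: 40
- min_fraction: 0.75
  usd: 80
- min_fraction: 0.90
  usd: 120
risk_estimator:
  intercept: -6
  threshold: 0
  weights:
    urge: 0.35
    negative_affect_stress: 0.35
    cigarette_availability: 0.15
    low_motivation: 0.15
    smoked_since_last: 1.0
rng_seed: 1
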