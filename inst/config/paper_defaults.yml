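# Canonical pipeline constants. Every stage parameter and calendar constant
# lives here; tests import these values instead of re-hardcoding them.
world:
  n_countries: 1
  n_metros_per_country: 2
  grid_size: 5
  cell_km: 2.0
  n_users: 2000
  observation_start: '2020-01-01'
  observation_end: '2020-12-31'
  pandemic_date: '2020-03-15'
  baseline_start: '2020-02-01'
  regression_start: '2020-04-11'
behavior:
  p_selfisolate_pre: 0.15
  rel_selfisolate: {high: 252.0, medium: 195.0, low: 141.0}
  rel_noncommute: {high: 93.5, medium: 78.0}
  rel_noncommute_low_by_work: {high: 82.0, low: 45.0}
  frac_low_home_high_work: 0.5
  commuter_fraction: 0.26
  rel_minutes_home: {high: 19.0, medium: 16.0, low: 13.0}
  other_duration_pre_min: 360.0
  commute_leave_min: 480.0
  commute_return_min: 1080.0
  transit_min: 30.0
  recovery_halflife_days: 300.0
  relocation_baseline_weekly: {urban_rural: 2.0e-4, rural_urban: 1.0e-4}
  rel_relocation: {high: 70.0, medium: 45.0, low: 21.0}
  relocation_halflife_days: 10.0
  relocation_window_weeks: 13
  penetration_weight: {high: 5.0, medium: 1.3, low: 0.7, rural: 0.5}
emission:
  pings_per_hour: 0.5
  accuracy_log_mean: 2.9957322736
  accuracy_log_sd: 0.5
  jitter_sd_m: 5.0
  p_active_day: 0.9
  frac_low_accuracy: 0.0
stages:
  d_max_m: 25.0
  t_min_s: 300.0
  max_mean_accuracy_m: 100.0
  eps_m: 25.0
  min_samples: 1
  window_days: 49
  step_days: 7
  min_visit_share: 0.20
  work_min_dwell_min: 60.0
  activity_threshold: 0.20
  high_pop_share: 0.20
  low_pop_share: 0.40
  n_perm: 20
  run_null_model: false
  run_panel: true
seed: 1
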