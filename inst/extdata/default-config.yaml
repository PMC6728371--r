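# icualarms default configuration.
# Each constant is tagged with its provenance:
#   [method]   printed in the published method this package implements
#   [decision] engineering default chosen by this package (method is silent)

alarm_time_s: 300                  # [method] alarms occur at the 300th second

preprocess:
  flat_min_duration_s: 2.0         # [method] constant value for at least 2 s
  flat_tol: 0                      # [decision] exact sample repetition
  baseline_order: 5                # [method] 5th-order polynomial baseline
  bp:                              # cited ABP abnormality criteria
    systolic_max_mmHg: 300
    diastolic_min_mmHg: 20
    map_min_mmHg: 30
    map_max_mmHg: 200
    pulse_pressure_min_mmHg: 20
    neg_slope_max_mmHg_per_s: -400 # -40 mmHg per 100 ms
    delta_sys_max_mmHg: 20
    delta_dia_max_mmHg: 20
    use_hr_criterion: false        # [method] heart-rate criterion disabled
    use_period_criterion: false    # [method] beat-period criterion disabled

detect:
  ssf_window_s: 0.128              # [decision] classical SSF window
  pulse_delay_s: null              # null => one SSF window  [decision]
  refractory_s: 0.2                # [decision] 300 bpm physiological ceiling
  qrs_scale: 2                     # [decision] dyadic scale for QRS search
  pulse_scale: 3                   # [decision] wider scale for SSF bumps
  threshold_rms_factor: 2.0        # [decision]
  searchback_factor: 1.66          # [decision]
  pair_window_s: 0.12              # [decision]
  bands:                           # [decision] band edges not printed
    low: [0.5, 6]
    qrs: [5, 25]
    high: [40, 110]
  envelope_smooth_s: 0.05          # [decision]
  kappa_pacing: 1.2                # [decision]
  kappa_twave: 0.3                 # [decision]
  vt_width_s: 0.14                 # [decision] wide complex > 140 ms
  vt_high_ratio: 0.8               # [decision]

features:
  windows:                         # [decision] per-type analysis windows
    ASYSTOLE: [284, 300]
    BRADYCARDIA: [280, 300]
    TACHYCARDIA: [280, 300]
    VFIB: [293, 300]
    VTACH: [290, 300]
  vf_augment_starts_s: [293, 294, 295, 296]  # [method] true-VF extraction x4
  template_half_window_s: 0.25     # [decision]
  sharpness_half_window_s: 0.06    # [decision]
  stability_band: 0.30             # [decision]
  periodicity_lag_s: [0.24, 2.4]   # [decision] 25-250 bpm
  swing_sub_window_s: 1.0          # [decision]
  spectral_band_hz: [0.5, 15]      # [decision]
  rate_resolution_bpm: 0.1         # [decision] rate quantization

model:
  n_trees: 301                     # [method]
  cost_fp: 1.0                     # [method] FP cost fixed at 1
  cost_fn_grid: [1.0, 1.1, 1.2, 1.3, 1.4, 1.5, 1.6, 1.7, 1.8, 1.9, 2.0]
                                   # [decision] superset of reported 1-1.4
  selection_repeats: 5             # [method] procedure performed five times
  plateau_tol: 0.5                 # [decision] plateau rule on median curve
  max_k: 10                        # [decision] score-curve length cap
  expand_factor: 1.2               # [method] final count = ceil(1.2 * x)

brady:
  threshold_bpm: 46                # [method]
  run_beats: 4                     # [method] slowest rate over 4 beats

synth:
  fs: 250                          # [method] challenge sampling rate
  duration_s: 300
  base_hr_bpm: 75                  # [decision]
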