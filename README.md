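# icualarms

Suppression of false arrhythmia alarms from ICU bedside monitors.

Most critical-arrhythmia alarms in intensive care are false, triggered by
noise or artifact in the monitored waveforms rather than by the patient.
`icualarms` classifies each alarm — asystole, extreme bradycardia, extreme
tachycardia, ventricular tachycardia (VT), or ventricular
flutter/fibrillation (VF) — as true or false, using only the ECG, PPG
and/or arterial-pressure waveforms recorded up to the alarm (second 300 of
each record, the real-time constraint).

The package is aimed at physiological-signal researchers working with
bedside-monitor data in the WFDB header+signal layout (e.g. the public
arrhythmia-alarm challenge training set), and at anyone who wants a fully
reproducible, synthetic-data-validated implementation of this alarm
classification approach.

## Method at its core

* **Signal processing** — flat-line screening (constant value ≥ 2 s),
  5th-order polynomial baseline removal, arterial-pressure abnormality
  criteria; a wavelet-transform QRS detector (modulus-maxima pairs at
  dyadic scales, adaptive thresholds, 0.2-s refractory, search-back) and a
  double slope-sum-function pulse-onset detector,
  `S2 = SSF(SSF(BP or PPG))`, insensitive to baseline wander; band
  amplitude envelopes reject pacing spikes and T-wave over-sensing and flag
  wide ventricular complexes.
* **Features** — per-channel signal quality indices (template correlation,
  peak-height stability, sharpness, periodicity), swing statistics, and
  arrhythmia-specific features: maximum RR interval and blank-area swing
  (asystole), minimum 5-beat / slowest 4-beat rate (bradycardia), maximum
  17-beat rate (tachycardia), spectral mean/median frequency and
  max-power ratio (VF), ventricular-run statistics (VT).  The rate of an
  *n*-beat run is `60·(n−1)/(t_n − t_1)` bpm.  True VF alarms contribute
  four feature rows (windows starting at the end of seconds 293–296).
* **Learning** — one cost-sensitive random forest per arrhythmia: 301
  trees, Gini splits, `sqrt(p)` features per split, uniform prior, FP cost
  fixed at 1 and FN cost tuned on a 1.0–2.0 grid by leave-one-record-out
  cross-validation; out-of-bag permutation importance drives forward
  feature selection (plateau point `x`, final count `⌈1.2·x⌉`, features
  mirrored across the two ECG leads).
* **Bradycardia rule** — on the channel with the highest correlation SQI,
  the alarm is true iff the slowest 4-consecutive-beat rate is below
  46 bpm; unreadable records fail safe to true.
* **Scoring** — `TPR = TP/(TP+FN)`, `TNR = TN/(TN+FP)`, and
  `Score = 100·(TP+TN)/(TP+TN+FP+5·FN)`: a missed true alarm costs five
  times a surviving false one.

A deterministic synthetic vital-sign generator (`synth_spec()`,
`generate_record()`, `generate_benchmark()`) produces records with exact
ground truth — including the artifact processes behind real false alarms —
so the entire pipeline is testable without clinical data.  See the vignette
`vignettes/alarm-classification-methods.Rmd` for the full account.

## Worked example

```r
library(icualarms)

dir <- file.path(tempdir(), "demo")
generate_benchmark(2, master_seed = 42, dir = dir)   # 20 labeled records
answers <- load_answers(file.path(dir, "answers.csv"))

rec <- read_alarm_record(file.path(dir, "a0001l.hea"), answers = answers)
rec
#> <alarm_record> a0001l  ASYSTOLE  label=TRUE_ALARM
#>   fs=250 Hz, 75000 samples (300 s), alarm at 300 s
#>   -  II       ECG
#>   -  V        ECG
#>   -  PLETH    PPG

pr <- process_record(rec)                 # masks, beats, envelopes
ft <- extract_features(rec, pr$beats, pr$masks, pr$env)
round(unlist(ft[, c("ecg1_max_rr", "ecg1_blank_area_swing",
                    "ecg1_sqi_correlation")]), 3)
#>           ecg1_max_rr ecg1_blank_area_swing  ecg1_sqi_correlation
#>                 6.440                 0.242                 0.990
```

This record is a true asystole: the longest beat-free interval on lead II
spans 6.44 s (≥ 4 s meets the definition), the signal inside that gap is
nearly flat (blank-area swing 0.242, against ~1+ when artifact merely hides
the beats), and the beats outside the gap have clean, repeatable morphology
(correlation SQI 0.99).  A classifier trained on such tables
(`extract_feature_tables()` → `train_alarm_models()` →
`classify_records()` → `evaluate_predictions()`) dispatches bradycardia
alarms to the rule and all other types to the per-arrhythmia forests.

The score's asymmetry in a single number:
`challenge_score(9, 0, 0, 1)` → `64.28571` — nine hits and a single missed
true alarm already cost a third of the score.

A command-line driver mirroring the pipeline
(`simulate` / `features` / `train` / `classify` / `eval`) ships in
`inst/cli/icualarms.R`:

```sh
Rscript inst/cli/icualarms.R simulate --out bench --n 10 --seed 1
Rscript inst/cli/icualarms.R features --records bench --out feats --training
```

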