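---
title: "Classifying ICU arrhythmia alarms: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying ICU arrhythmia alarms: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icualarms)
```

## The problem

Bedside monitors in intensive care units raise an alarm whenever their
built-in detectors believe a life-threatening arrhythmia is in progress:
asystole, extreme bradycardia, extreme tachycardia, ventricular tachycardia
(VT), or ventricular flutter/fibrillation (VF).  The large majority of these
alarms are false, usually because noise or artifact in the ECG, the
photoplethysmogram (PPG) or the arterial blood pressure (ABP) waveform
mimics the arrhythmia.  `icualarms` classifies each alarm as true or false
using only the waveforms recorded up to the moment of the alarm (by
convention, second 300 of a 300-s record), the constraint a real-time
suppression system must live with.

The pipeline has four stages:

1. **Preprocessing** — flat-line screening (a constant value for at least
   2 s means a disconnected probe), 5th-order polynomial baseline removal on
   ECG analysis windows, and the classical ABP abnormality criteria
   (pressure ranges, pulse pressure, slew rate, beat-to-beat jumps).
2. **Beat detection** — a wavelet-transform QRS detector on ECG and a
   double slope-sum-function (SSF) onset detector on pulse channels, with
   band-envelope screening of pacing spikes and T-wave over-sensing and
   flagging of wide ventricular complexes.
3. **Feature extraction** — signal quality indices (SQIs) on every channel
   plus features matching each arrhythmia's definition, over a short
   pre-alarm analysis window.
4. **Classification** — a cost-sensitive random forest per arrhythmia type,
   with out-of-bag permutation importance, forward feature selection, and a
   grid search over the false-negative cost; bradycardia alone is decided by
   a transparent rule on the most reliable channel.

## Detectors

**QRS.** The ECG is decomposed with an à-trous dyadic wavelet transform
(quadratic-spline-like filters `[1,3,3,1]/8` and `[2,-2]`).  The detail
signal at scale $2^2$ behaves like a smoothed derivative: an R wave is a
positive–negative modulus-maxima pair whose zero crossing marks the peak.
Candidates must exceed an adaptive threshold (2 × the RMS of the detail
signal over the analysis segment), are separated by a 0.2-s refractory
period (a 300-bpm physiological ceiling), and long RR gaps are re-scanned at
half threshold (search-back).  Peak times are refined to sub-sample
precision by parabolic interpolation, which matters at decision boundaries
(see *Numerical choices*).  Because the threshold is relative, detection is
invariant to amplitude scaling and offsets.

**Pulse onsets.** For BP/PPG the SSF — the windowed sum of positive first
differences over a trailing 128-ms window — is applied twice, with no
low-pass prefiltering.  `SSF(SSF(x))` has sharp QRS-like bumps at each
upstroke; their peaks are found with the same wavelet peak detector (at
scale $2^3$, matching the wider bumps) and shifted back by one SSF window to
land on the pulse onset.  The test suite asserts that every onset on the
package's synthetic pulses is recovered within 60 ms, with identical
recovery when a 0.2-Hz baseline oscillation as large as the pulse pressure
is added — the SSF only sees local slopes, which is the point of using it.

**Envelope screening.** Three zero-phase Butterworth band envelopes
(low 0.5–6 Hz, QRS 5–25 Hz, high 40–110 Hz, rectified and smoothed over
50 ms) support two rejection rules and one flag:

* *pacing spike*: high-band envelope at the fiducial > 1.2 × QRS-band
  envelope (a one-sample impulse is mostly high-band; a QRS is not);
* *T-wave over-sensing*: QRS-band envelope < 0.3 × the median over accepted
  beats (T waves carry little 5–25 Hz energy);
* *ventricular*: QRS-band envelope above half its beat-local maximum for
  more than 140 ms with little high-band content — a wide, smooth complex.

The band edges and constants are engineering defaults of this package,
calibrated on the synthetic waveforms (all in `default_config()$detect` and
`inst/extdata/default-config.yaml` with provenance tags).  The envelope is
read at the fiducial sample itself: a local-maximum readout was tried and
rejected because it lets a spike tens of milliseconds away contaminate the
ratio of a genuine beat, causing runs of good beats to be discarded when an
asynchronous pacing train sweeps across the rhythm.

## Features

Every available channel (two ECG leads first, then PPG/ABP) contributes a
quality block and a swing block; each arrhythmia adds features that mirror
its definition.  Rates over $n$-beat runs are $60(n-1)/(t_n-t_1)$ bpm.

| group | features | note |
|---|---|---|
| SQI | template correlation, peak-height stability, sharpness, periodicity | all scale-invariant |
| swing | min / max / mean of 1-s sub-window (max − min) | masked spans skipped |
| asystole | max RR interval, blank-area swing | window edges count as virtual beats, so an empty window yields the window length |
| bradycardia | minimum 5-beat rate, slowest 4-beat rate | |
| tachycardia | maximum 17-beat rate | |
| VF | spectral mean/median frequency, max-power ratio (ECG only) | Hann-tapered periodogram, 0.5–15 Hz |
| VT | max ventricular-run length and rate, envelope width (ECG only) | |

Definitional details worth recording:

* *Sharpness* divides the fiducial amplitude by the mean absolute signal in
  ±60 ms (fiducial ±1 sample excluded).  An exactly silent neighborhood is
  floored at 1% of the peak, capping sharpness at 100, so an impulse train
  on a quiet background reads as maximally sharp instead of undefined.
* *Blank-area swing* is the swing inside the longest inter-beat gap, with a
  0.4-s guard next to the bounding beats so their QRS/T/P deflections do not
  count as activity inside the "blank" area.
* *Max-power ratio* sums the peak periodogram bin and its two neighbors
  before dividing by total band power; a Hann taper spreads a pure tone over
  exactly three bins, and without this a sinusoid could never score above
  ~0.67.
* Analysis windows (seconds before the 300-s alarm): asystole [284, 300],
  bradycardia and tachycardia [280, 300], VT [290, 300], VF [293, 300].
  For a *true* VF alarm in training mode, extraction runs four times, with
  windows starting at the end of seconds 293–296, because the oscillation
  onset is only guaranteed to fall within 10 s of the alarm.  The VF
  prediction window was aligned to [293, 300] (the earliest augmented
  start) so that prediction-time feature vectors come from the same window
  length as the true-VF training rows; with a longer window the true rows
  would systematically mix pre-VF rhythm at prediction time only.

## The classifier

Each arrhythmia type gets its own bagged-tree ensemble: 301 trees, Gini
splits, `sqrt(p)` candidate features per split, uniform class prior.
Misclassification costs (false positive fixed at 1, false negative ≥ 1)
multiply the prior into class weights used both in tree growing and in the
vote aggregation; with equal costs this reduces to a plain majority-vote
forest, which is asserted in the tests.  Missing values (absent channels,
too few beats) are imputed with training-fold medians; a prediction from an
all-missing vector therefore falls back deterministically to the
cost-weighted prior class, and ties break toward `TRUE_ALARM` — every
fail-safe in the package errs toward keeping the alarm.

**Importance and selection.** Feature importance is the out-of-bag
permutation importance (per-tree OOB error increase under permutation,
averaged over trees, divided by the ensemble standard deviation; a constant
feature scores exactly 0).  Cross-validation leaves one *record* out, so the
four augmented rows of a true VF alarm never straddle the train/test split.
Forward selection ranks features by mean importance across the folds, scores
the top-$k$ subsets for $k = 1 \dots K$, and repeats the whole procedure
five times with distinct seeds; $x$ is the smallest $k$ whose median score
is within 0.5 score units of the best (the plateau rule), and the final set
keeps the top $\lceil 1.2x \rceil$ features, symmetrized so a feature chosen
on one ECG lead brings its twin on the other.  The curve length is capped at
$K = 10$: on this package's feature sets the median curve plateaus by
$k \approx 4$, and each extra curve point costs a full leave-one-record-out
pass.  The false-negative cost is then tuned by grid search over
1.0–2.0 in steps of 0.1 (ties to the smallest cost), and the final forest is
refit on all rows.  All randomness descends from one master seed through a
fixed offset scheme, so a training run is exactly reproducible.

**Bradycardia.** The final implementation replaces the forest for
bradycardia with a rule: pick the channel with the highest
template-correlation SQI (ties to the first channel, ECG leads first),
compute the slowest rate over 4 consecutive beats in the analysis window,
and call the alarm true iff that rate is strictly below 46 bpm.  Records on
which no channel yields 3 beats are called true — missing an extreme
bradycardia carries a fivefold penalty.  Measured rates are quantized to
0.1 bpm before the comparison: detection jitter is below a millisecond on
clean signals, but the minimum over many 4-beat runs of an unbiased jitter
is biased downward, and without quantization a record beating at exactly
46 bpm would drift infinitesimally below the strict threshold.

**Scoring.** Performance is reported as TP rate, TN rate, and the score
$100(TP+TN)/(TP+TN+FP+5FN)$, whose fivefold FN weight encodes that a missed
true alarm is far worse than an unsuppressed false one.  Pooled scores are
computed over all records jointly, not averaged over types.

## The synthetic test bed

Real challenge records are not shipped; the `synth` module generates
records with exact ground truth instead.  ECG is a sum of per-beat Ricker
(Gaussian second-derivative) templates — narrow (σ = 20 ms) for normal
beats, wide (σ = 40 ms) for ventricular ones — plus small P/T bumps; VF is
an amplitude-modulated 4–7 Hz sinusoid; pulse channels are asymmetric
raised-cosine/exponential pulses 200 ms after each QRS (ABP at 120/80 mmHg).
Background: 75 bpm with 2% RR jitter, white noise (σ = 0.02 of QRS
amplitude), slow sinusoidal wander.  True-alarm episodes satisfy the
standard definitions (gap ≥ 4 s; < 40 bpm × 5 beats; > 140 bpm × 17 beats;
≥ 5 ventricular beats > 100 bpm; oscillation ≥ 4 s) with the qualifying
episode overlapping the final 10 s; false-alarm scenarios keep the rhythm
innocent and add the artifact that fooled the monitor: broadband bursts,
brief flat lines, slow asynchronous pacing trains, an unreadable PPG next
to a clean ECG.  Each generated record is validated against the truth
annotator at generation time; a contradictory request errors out.

Boundary semantics are pinned so threshold-recovery sweeps are exact:
"at least" is inclusive, "lower/higher than" strict, with a $10^{-9}$ guard
so an exactly-boundary input is classified by the strict reading rather
than by floating-point noise.

What the generator does *not* emulate — realistic QRS morphology variation,
respiration, ectopy, electrode motion artifact with its characteristic
spectra, atrial fibrillation — bounds what passing tests show: they
demonstrate that the detectors, features, selection machinery and
fail-safes implement the intended method and separate the intended
mechanisms, not that the trained forests would reach any particular score
on clinical data.

## Numerical choices and degenerate inputs

* Flat-line tolerance is 0 raw units (exactly repeated samples); the 2-s
  minimum is compared as `run length ≥ ceiling(2 fs − ε)`.
* Baseline fits use orthogonal polynomials (`stats::poly`) for conditioning;
  windows shorter than `order + 1` samples are an error.
* Sub-sample peak refinement is a three-point parabola, falling back to the
  grid peak when degenerate.
* The ABP negative-slope criterion fires below −400 mmHg/s
  (−40 mmHg per 100 ms).  A normal pressure decay is on the order of
  −60 mmHg/s, so a threshold of −40 mmHg/s would flag every healthy beat;
  the per-100-ms reading is the one consistent with a clean 120/80 waveform
  producing no flags.
* Single-class cross-validation folds (possible only on tiny tables) vote
  their class deterministically instead of erroring.
* Heart-rate-range and beat-period-change ABP criteria are implemented but
  disabled by default, matching the method's stated exclusions.

## Problem sizes used in validation

The shipped test suite regenerates everything from code: detector recovery
uses 20 clean 60-s records per detector; the oracle equivalence checks run
on 1000 random beat trains; the cost-sensitivity trend is measured on a
150-row two-feature Gaussian-overlap table over 5 seeds (large enough that
one flipped record moves a rate by less than 1.4 points); the
feature-separation and end-to-end checks
share one cached benchmark of 50 records per arrhythmia × label (500
records, 100 alarms per type), train with the default settings above, and
score a fresh 60-record held-out benchmark.  These sizes were chosen as the
smallest at which the checks are stable across seeds; the acceptance script
(`scripts/acceptance.R`) sweeps only constructed inputs and runs in well
under a minute.

## Known limitations

* The wavelet detector is a faithful re-implementation of the cited
  delineation approach's structure, not a bit-compatible port; validation
  is by synthetic recovery, not beat-file identity.
* Exact published per-arrhythmia feature lists, analysis-window lengths and
  tuned FN costs are not reprinted in the available text; the registry and
  windows here are reconstructions, declared in the config with provenance
  tags, and the FN-cost grid recovers dataset-specific optima rather than
  asserting published ones.
* Class weights emulate a native misclassification-cost matrix; for
  two-class problems the two are equivalent in expectation, but individual
  trees may differ from a cost-matrix implementation.
* No retrospective mode: signals after the alarm are never used.
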