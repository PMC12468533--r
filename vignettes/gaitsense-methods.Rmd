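---
title: "gaitsense: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{gaitsense: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitsense)
```

This vignette is the package's own account of the science it
implements: the signal models behind each stage, the tunable parameters
and their defaults, what the synthetic-data generator does and does not
emulate, and the places where the design was genuinely open and a
choice had to be made.

## The measurement setting

The pipeline targets a two-sensor wearable: a 6-axis IMU (3-axis
accelerometer in m/s², 3-axis gyroscope in °/s) strapped at the lumbar
spine, and a polymer-optical-fiber chest belt operated in transmission
mode. Chest-wall motion during breathing curves the fiber and modulates
the transmitted intensity, so the respiratory rate appears as the
dominant frequency of the intensity trace. The axis convention is fixed
and documented (x anteroposterior, y mediolateral, z vertical) because
the hardware itself imposes none; all per-axis quantities are relative
to it.

## Breathing-rate estimation

The intensity trace is modeled as
`baseline + A·sin(2π(BR/60)t) + drift·t + noise`. The estimator
(`estimate_breathing_rate()`):

1. removes the mean and a fitted linear drift;
2. applies a Hann taper;
3. zero-pads to at least 8× the record length (next power of two);
4. takes the maximum-magnitude FFT bin inside the search band;
5. refines the peak by parabolic interpolation over the peak bin and
   its two neighbors, clamped to ±½ bin.

The sub-bin refinement is not cosmetic: a 60 s record has a raw bin
width of 1/60 Hz, i.e. a whole breath per minute, far coarser than the
sub-BPM accuracy the sensor principle supports. With tapering, padding
and interpolation the estimator resolves a clean tone to a few
thousandths of a BPM, and the noise-robustness property test checks
that single-tone traces at 10 dB SNR stay within 0.6 BPM over 100
seeded trials.

Parameters, with defaults:

* `band = c(0.05, 1.0)` Hz (3–60 BPM): excludes residual drift below
  and cardiac/motion harmonics above the respiratory band.
* `pad_factor = 8`: padding beyond 8× changes estimates by less than
  the interpolation error.
* `min_peak_frac = 0.05`: a peak is accepted only if its bin carries at
  least 5% of the in-band power. A pure tone concentrates far more than
  this in the peak bin even after padding spreads its main lobe, while
  the maximum bin of in-band white noise carries roughly
  log(#bins)/#bins ≈ 1% — so the threshold separates the two regimes
  with a wide margin. Flat or noise-only traces raise a classed
  `no peak` error; sliding-window analysis flags such windows instead
  of dropping them.

Record durations are counted as n/rate (each sample covers one
sampling interval), so a "120 s" record yields exactly
⌊(120 − 40)/20⌋ + 1 = 5 sliding 40 s windows at a 20 s step.

### Regimes and condition bins

Clinical regimes partition (0, ∞): bradypnea below 12 BPM, normal 12–20
BPM with both boundaries inclusive (reading "between 12 and 20"
inclusively), tachypnea above 20 BPM.

The clustering condition bins are reported as: condition 0 below
10 BPM, condition 1 at 11–13, condition 2 at 14–16, condition 3 at
17–19, condition 5 above 19. Two quirks are carried deliberately:
the labels skip "4" (they are reported that way, and relabeling would
break comparability), and the printed bins leave gaps at 10–11, 13–14
and 16–17. Since the printed bins cannot be a partition, gap values are
assigned to the nearest bin edge, making the effective cut points 10.5,
13.5, 16.5 and 19 BPM; 19 itself belongs to condition 3.

### Cluster-count selection

`cluster_breathing_rates()` runs `stats::kmeans` (300 iteration cap, 10
restarts) at every k in 2..20 and scores each partition with the mean
silhouette width (`cluster::silhouette`). The silhouette curve over k
is typically multi-peaked on breathing-rate data; the selection rule is
the global argmax with ties broken toward the smaller k — the simplest
rule that is deterministic and favors parsimony. The full curve is
returned so a user can inspect competing peaks. With fewer than
k_max + 1 distinct samples the range is truncated; fewer than three
distinct samples is an error.

## TUG segmentation

### Features

Windowed statistics (per axis: mean, SD, min, max, RMS) over 0.5 s
windows hopped by 0.1 s. The window must resolve the shortest phase —
sit-to-stand lasts on the order of 1.26 s — while containing enough
samples for stable statistics; 0.5 s at 100 Hz gives 50 samples.

The device's classifier consumed the accelerometers, gyroscopes *and
the time stamp* as inputs. The timestamp is a double-edged feature:
within a protocol where every trial follows the same phase order at
similar times it is genuinely informative, but with one trial per
recording it lets a model shortcut to time→phase. `window_features()`
therefore defaults to `include_timestamp = FALSE`, and the protocol
runner `run_tug_acceptance()` enables it explicitly, reproducing the
original input set. It matters for one specific reason: the forward
walk (class 2) and return walk (class 4) are statistically identical in
a window — both are cadence-frequency oscillations — and only temporal
context separates them, exactly as in real lumbar-IMU recordings.

### Classifier

`randomForest` with 54 trees and 6 candidate features per split, a
stratified 70/30 window split (every class contributes 70% of its
windows to training, so both partitions contain all seven classes), and
stratified 5-fold cross-validation on the training portion. All
randomness flows from `classifier_config(seed = )`. Per-class accuracy
is the recall — the diagonal confusion-matrix count over the true-class
row sum — the standard reading of a per-class figure on a confusion
matrix.

### Intervals, smoothing and the label grid

Each phase's interval is last-detection minus first-detection time; the
total time is the sum of the six phase intervals (the alternative
last(6) − first(1) reading is available from the same interval table
but the sum is the normative method). Two guards stand between raw
window predictions and that rule:

* **Majority smoothing** (`smooth_labels()`, 0.5 s kernel): the
  first/last rule has no robustness — a single stray "phase 5" window
  during the first walk would extend phase 5's interval across half the
  trial — so isolated misclassifications are removed by a sliding-mode
  filter first. Ties keep the current label when it is among the modes.
* **Resampling to sensor timestamps** (`resample_labels()`):
  classifications live on the window-center grid (centers span
  [w/2, T − w/2] with a step-sized spacing), and reading first/last
  times directly off that grid truncates every phase by half a step at
  each boundary and the last phase by half a window at the trial end —
  a systematic undercount of nearly a second per trial at the default
  geometry. The detection rule is defined on the time stamps of the
  sensors, so window labels are decoded back to the sensor grid by
  nearest-center lookup, which places phase boundaries halfway between
  adjacent window centers and makes the boundary error zero-mean. The
  end-to-end property test requires the recovered total time within
  0.5 s of truth in at least 90% of seeded default-noise trials.

On the simulator's own sample grid, extraction applied to the true
labels reproduces the stored truth intervals exactly; against the
generating continuous durations a one-sample-spacing (0.01 s)
discrepancy per phase is inherent to sampling, and the tests assert
exactly that.

### Fall risk

The conventional total-time rule: below 10 s low risk, 10–19 s
moderate, above 20 s high. As printed the rule leaves [19, 20) s
unassigned; because the TUG literature the rule comes from uses 20 s as
the moderate/high cutoff, moderate covers [10, 20) and high [20, ∞).
Every result object embeds the rule text and a version string so a
downstream report is never ambiguous about which resolution produced
it. One reported phase-naming inconsistency is resolved the same way:
class 1 is implemented as sit-to-stand (consistent with the worked
interval example and the event order of the test), class 6 as
stand-to-sit.

## Balance regression

Quiet-stance sway is a per-trial scalar problem fed by a time series.
Each trial is summarized by aggregating its window features (mean and
SD of every window feature across the trial, 60 features), and three
Random Forest regressors — one per index, behind a single
`balance_regressor` object — map them to anterior displacement, medial
displacement and LFS. Fitting one forest per output makes the
"multi-output regressor agrees with independently trained single-output
models" property true by construction. Training uses a seeded 70/30
trial split; reported RMSEs are held-out.

LFS deserves a note: it is a postural-stability index with no
closed-form definition available here, so the package never computes it
from signal — it is a latent ground-truth scalar attached to each
simulated trial, and the regressor learns it from reference data,
which mirrors how the real system was trained against a commercial
reference device.

Condition comparisons report means per stance and percent changes to
one decimal place, with reductions expressed as 100·(wide −
narrow)/wide.

## The synthetic-signal generator

The generator is the package's test bed; its defaults are fixed study
conditions, not tuning knobs.

**TUG trials.** Piecewise deterministic templates plus additive
Gaussian sensor noise: sit-to-stand is a half-sine pitch
angular-velocity pulse (60 °/s peak) with a vertical-acceleration spike
(2 m/s²); walking phases are cadence-frequency oscillations (default 2
steps/s, ~1 m/s² anteroposterior); turns are raised-cosine-edged yaw
plateaus of opposite sign whose area integrates to a 180° turn;
stand-to-sit mirrors the transfer pulse. Default phase durations are
2.00 s idle then 1.26, 2.80, 1.74, 2.80, 1.20, 1.16 s — sit-to-stand at
1.26 s and classes 1..6 summing to 10.96 s, a typical healthy
completion time. Labels switch instantaneously at phase boundaries,
matching the first/last-detection semantics. Sensor noise defaults to
0.1 m/s² and 1 °/s, typical MEMS figures at 100 Hz.

**Balance trials.** Sway displacement is band-pass-filtered white noise
(Butterworth order 2 via the `signal` package), scaled so the peak
excursion equals the trial's ground-truth amplitude; acceleration is
its second time derivative. The upper pass-band edge scales as
0.8 Hz/LFS: a more stable subject sways more smoothly, which both makes
LFS physically meaningful and gives the regressor a frequency-content
signal to learn it from. Wide-base defaults are 33 mm anterior, 6 mm
medial, LFS 1.68; narrow stance multiplies these by fixed factors
(20/33, 16/6, 0.92/1.68). The induced accelerations land in the few
tenths of m/s² and the narrow base has strictly larger medial
acceleration variance — both consistent with quiet-stance recordings.

**Breathing traces.** Sinusoid plus optional drift and Gaussian noise;
default amplitude 0.45 a.u. (0.9 a.u. peak-to-peak) and noise SD 5% of
amplitude; 60 s records at 50 Hz. The metronome protocol is five
repeats at each of 10, 13, 15, 17 and 20 BPM.

**Rate sample sets.** Five Gaussian bands centered at 8, 12, 15, 18 and
22 BPM (the condition-bin centers) with SD 0.5 BPM, truncated to
(0, 60), evenly allocated — 29 per band at the 145-sample default.

**Cohort variation.** `random_profiles()` jitters durations
(multiplicative, SD 10%), cadence (SD 0.15 steps/s), sway amplitudes
(SD 4 and 1.5 mm), LFS (SD 0.25) and draws breathing rates uniformly on
10–20 BPM — spreads a clinician would call typical across an elderly
cohort.

Sampling rates are nowhere reported for the original device; 100 Hz
(IMU) and 50 Hz (optical) are declared defaults chosen as typical
wearable rates that resolve the gait and respiratory bands,
configurable throughout.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: soft-tissue and strap artifacts,
inter-step variability and asymmetric gait, magnetometer-free heading
drift during turns, belt slippage and amplitude nonstationarity in the
optical channel, postural strategies (ankle vs hip) in sway, and any
correlation structure between breathing and movement. Classifier
accuracies on these clean templates are upper bounds; the pipeline's
correctness properties (interval semantics, rule boundaries,
determinism, error handling) transfer, its error magnitudes need not.

## Numerical choices and degenerate inputs

* Zero-noise generation skips the RNG entirely, so noiseless traces are
  bit-identical across seeds.
* Parabolic peak interpolation is clamped to ±½ bin and degrades to the
  raw bin at spectrum edges or flat curvature.
* `smooth_labels(kernel = 0)` is the identity; kernels shorter than one
  grid step likewise.
* Absent phase classes yield zero durations and warning flags, never
  errors; empty feature inputs predict empty outputs.
* Orientation estimation initializes from the first accelerometer
  sample, holds gyro-only updates through free-fall windows
  (‖a‖ < 2 m/s²), and converges to the accelerometer inclination for
  static inputs for any blending constant α < 1 (default 0.98).
* Reports serialize floating point at fixed precision with no
  wall-clock fields, so identical config + seed reproduce files
  byte-for-byte; configs reject unknown keys.

## Problem sizes

The bundled protocols run at desk scale, chosen so the whole validation
suite completes in well under a minute on one CPU while leaving
comfortable statistical margins: 40 TUG trials (≈ 5,000 windows), 200
balance trials, 25 metronome recordings, 145-sample clustering sets.
`n_trials` scales all of them up.

## Known limitations

* The TUG classifier is trained and evaluated per-window; per-event
  accuracy is not computed.
* The double-integration pathway to linear displacement is exposed only
  through orientation/feature utilities; it is not part of any fitted
  model.
* LFS has no analytic definition in the package, so a trained
  `balance_regressor` is only as meaningful as its reference source.
* The condition-bin labels (0, 1, 2, 3, 5) and their gap handling are a
  faithful carry-over of reported bins, not a claim that this is the
  ideal discretization.
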