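# gaitsense

Signal-processing and machine-learning pipeline for a low-cost wearable
monitoring system that combines a 6-axis inertial measurement unit (IMU)
worn at the lumbar spine (L4–L5) with a fiber-optic chest belt whose
transmitted intensity is modulated by chest-wall curvature during
breathing. The package implements the complete analysis chain for the
clinical protocols such a device is used in — the Timed-Up-and-Go (TUG)
mobility test, quiet-stance balance testing, and continuous
breathing-rate monitoring — and ships a synthetic-signal generator with
known ground truth so that every stage can be exercised and validated
without access to recorded subject data.

## What it computes

**Breathing rate.** The chest-belt intensity signal is periodic at the
respiratory frequency. `estimate_breathing_rate()` removes the mean and
linear drift, applies a Hann taper, zero-pads the FFT (≥ 8×) and refines
the in-band spectral peak by parabolic interpolation, returning
BR = 60 · f_peak in breaths/min (BPM). Rates are classed into clinical
regimes (bradypnea < 12 BPM, normal 12–20 BPM, tachypnea > 20 BPM), and
`cluster_breathing_rates()` groups rate samples by K-means with the
number of clusters k ∈ [2, 20] selected by the mean silhouette width.

**TUG phase segmentation.** The TUG test decomposes into seven phases,
coded 0–6: start/idle, sit-to-stand, forward walk, first turn, return
walk, second turn, stand-to-sit. Sliding-window IMU statistics (per-axis
mean, SD, min, max, RMS over 0.5 s windows) feed a Random Forest
classifier (54 trees, 6 candidate features per split, stratified 70/30
split, 5-fold CV). Each phase's interval is the time difference between
its first and last classification — first detected at 0.2 s and last at
1.2 s gives a 1 s interval — and the total time, the sum of the six
phase intervals, feeds the conventional fall-risk rule (< 10 s low,
10–20 s moderate, ≥ 20 s high).

**Balance indices.** Quiet-stance trials (wide- and narrow-base) are
summarized into per-trial aggregated IMU features, from which a
multi-output Random Forest regressor estimates the anterior and medial
displacement (mm) and the Local Fractal Stability (LFS), a dimensionless
postural-control index that is learned from reference data rather than
computed from a formula. `compare_conditions()` reports condition means
and percent changes between stances.

## Worked example

```r
library(gaitsense)

# A 60 s chest-belt recording breathing at 20.4 BPM (0.34 Hz)
tr  <- simulate_breathing_trace(bpm = 20.4, duration = 60, rate = 50, seed = 1)
estimate_breathing_rate(tr)
#> <breathing_estimate> 20.40 BPM (peak 0.3400 Hz, tachypnea), window [0, 59.98] s

# End-to-end TUG protocol: simulate 40 labeled trials, train the
# Random Forest segmenter, recover intervals and total times
run_tug_acceptance(seed = 1, n_trials = 40)
#> <tug_protocol_result> 40 trials
#>   min held-out per-class accuracy: 0.9722
#>   median |total time error|: 0.076 s

# Breathing-regime clustering of 145 rate samples
cluster_breathing_rates(simulate_br_samples(145, seed = 3)$bpm, seed = 3)
#> <br_clustering> 145 samples, silhouette-selected k = 5
#>   centers (BPM): 7.90, 11.99, 15.17, 17.97, 21.86
#>   best silhouette: 0.840

# Balance regression on 200 simulated quiet-stance trials
ba <- run_balance_acceptance(seed = 1, n_trials = 200)
ba
#> <balance_protocol_result> 200 trials (60 held out)
#>   held-out RMSE: anterior 2.97 mm, medial 1.84 mm, LFS 0.121
ba$comparison
#> <balance_comparison> condition means and changes (narrow vs wide)
#>   index           wide mean  narrow mean     change
#>   anterior_mm         32.66        19.96      38.9% reduction
#>   medial_mm            6.06        15.44     154.9% increase
#>   lfs                  1.70         0.93      45.4% reduction
```

The minimum per-class accuracy says the weakest of the seven TUG phases
is still recognized on more than 97% of held-out windows; the balance
RMSEs are held-out errors of the regressor against the simulator's
ground truth; the clustering recovers the five planted rate bands.

A thin command-line front end over the same functions is installed at
`inst/cli/gaitsense.R`
(`Rscript inst/cli/gaitsense.R simulate --kind tug --seed 3 --out dir`).

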