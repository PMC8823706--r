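# ahvtools

Analysis of angular head velocity (AHV) coding in cortical single-unit
recordings, packaged as a tested, reusable R pipeline. It is aimed at
systems neuroscientists who record spike trains from freely moving and
head-fixed rodents and want to (1) classify units as head-direction-,
AHV- or locomotion-speed-tuned against permutation nulls, (2) track the
same units across recording sessions, (3) quantify responses to passive
vestibular/visual rotation, (4) measure single-cell and population-level
discrimination of rotation direction and speed, (5) detect putative
monosynaptic connections, and (6) score go/no-go rotation-discrimination
psychophysics. Seeded synthetic-data generators provide ground truth for
every stage, so the whole pipeline is verifiable end to end.

## The statistics at the core

* **Tuning classification.** Head direction is the angle of the line
  perpendicular to the inter-ear axis; AHV is its circular derivative
  over a trailing 200-ms window (positive = clockwise), and speed comes
  from body displacement at 40 frames/s. Occupancy-weighted tuning
  curves use 6° (HD), 6°/s (AHV, over ±80°/s) and 1 cm/s (speed,
  ≤ 20 cm/s) bins. AHV and speed scores are |Pearson r| between binned
  rate and the covariate; significance comes from a spike-time-shift
  null (each permutation circularly shifts the whole train by
  U(20 s, T − 20 s)). HD cells must additionally pass an
  occupancy-weighted Rayleigh test (p < 0.01) and exceed the 99th
  percentile of a pooled population null in two epochs.
* **Cross-session unit matching.** For each head-fixed ("Fix") unit,
  candidate freely moving ("Free") units on neighbouring channels are
  scored with a weighted sum of three similarity-category L2 norms —
  local waveform features compared through the proportional difference
  `F(x, y) = max(0, 1 − |(x − y)/x|)`, global dynamic-time-warped
  waveform metrics, and inter-spike-interval histogram correlation and
  intersection `Σ min(h₁, h₂) / Σ max(h₁, h₂)` — with weights
  (1/9, 4/9, 4/9). Accepted matches must satisfy ISI correlation > 0.7,
  all four local features > 0.7, waveform correlation > 0.95 and
  waveform difference < 0.3.
* **Rotation analysis.** Velocity tuning at 5°/s bins with bin-shuffle
  nulls, the rotation modulation index `|R̄rot − R̄base| / R̄base`,
  direction-selectivity ROC, and active-versus-passive tuning-curve
  correlation.
* **Discrimination.** Rectified ROC AUCs (speed bin peaking at 10°/s
  versus bins peaking at 15–80°/s; CW versus CCW) with 99% DeLong
  confidence intervals; linear-discriminant population decoding with
  analytic (Ledoit–Wolf) shrinkage, balanced leave-one-trial-per-class-out
  cross-validation and bootstrap population-size curves.
* **Connectivity.** Cross-correlograms (0.5-ms bins, ±50 ms) with
  Fourier-smoothed baselines and extreme Poisson confidence bands
  (0.0001–99.9999 percentile); excitatory = ≥ 2 bins above the band at
  1.5–4 ms, inhibitory = ≥ 3 bins below.
* **Behaviour.** Go/no-go scoring (S+ correct = licking in ≥ 2 of the
  250-ms bins after the velocity peak), block accuracy = mean of the
  percent-correct S+ and S− trials, and 4-parameter logistic
  psychometric fits with the floor bounded at the 50% chance level.

## Worked example

```r
library(ahvtools)

# a 20-minute open-field session and one AHV-tuned unit
tr  <- simulateTrajectory(1200, seed = 2)
kin <- computeKinematics(tr)
unit <- simulateTunedSpikes(kin, neuronSpec(baselineRate = 2,
                                            ahvGainRight = 0.2), seed = 3)
res <- classifyAHV(unit, kin, nPerm = 1000, seed = 4)
res$isAHV;  res$subtype;  round(res$slopeRight, 3)
#> [1] TRUE
#> [1] "unidirectional_right"
#> [1] 0.185
```

The unit is classified as a right-turn (clockwise) AHV cell and the
fitted slope, 0.185 Hz/(°/s), recovers the generating gain of
0.2 Hz/(°/s) to within the smoothing-induced attenuation of the
kinematic estimate (~8%). The stimulus generator reproduces the passive
rotation protocol:

```r
p <- makeRotationProfile(90, 7)   # 90 deg amplitude, 7 s period
max(abs(profileVelocity(p)))
#> [1] 80.78381                    # peak speed, deg/s
```

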