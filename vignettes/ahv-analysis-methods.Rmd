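---
title: "Methods: angular head velocity analysis in ahvtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: angular head velocity analysis in ahvtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahvtools)
```

# Scope and data model

ahvtools analyses single-unit spike trains recorded while an animal
either explores an arena freely (tracked at a nominal 40 frames/s) or
sits head-fixed on a rotating platform. All times are seconds from
session start in double precision; all angles are degrees with heading
in [0, 360); angular head velocity (AHV) is signed with **positive =
rightward/clockwise** head turns. Four S4 classes carry the central
data: `SpikeTrain` (strictly ascending spike times), `UnitWaveform`
(mean channels × time waveform in µV with channel geometry),
`VelocityProfile` (stimulus position/velocity, with a validity check
that velocity is the derivative of position and that profiles start and
end at rest) and `KinematicSeries` (per-frame heading, AHV, speed).
Tabular objects (tracking, trial tables, result tables) are plain data
frames. Curation (e.g. the 900-spike minimum) flags units rather than
deleting them.

# Kinematics

Head direction is the angle between the horizontal axis and the line
perpendicular to the axis joining the two tracked ears. The heading
series is smoothed with a sliding **circular** mean (unit-vector
averaging, default 50 ms): a scalar filter would create artifacts at
the 0/360 wrap. AHV at frame *k* is the unwrapped heading change over a
**trailing** 200-ms window divided by the window length, so the value at
a time point only uses data up to that point; the first window of each
session is NA. Locomotion speed is frame-to-frame body displacement
divided by the frame interval, mean-filtered with the same width.
Because of the smoothing and finite derivative window the recovered AHV
is a slightly low-pass version of the true angular velocity; the slope
of rate–AHV fits is attenuated by a few percent, which is visible (and
accepted) in the slope-recovery checks.

# Tuning classification

Tuning curves are occupancy-weighted: total spikes in a bin divided by
total dwell time. Grids are 6° for heading, 6°/s for AHV and 1 cm/s for
speed (speeds above 20 cm/s are excluded). "6°/s up to 80°/s" is not a
whole number of bins, so the AHV grid uses whole bins spanning
[−78, 78] °/s. Two numerical rules go beyond the obvious definitions:

* **Zero-occupancy bins are excluded, never zero-filled**, and
* bins with **less than 1 s of dwell** (`minOccupancy`) are excluded
  from correlations and fits. A bin visited for two or three frames can
  produce a 3-spike, 40-Hz rate estimate that dominates a Pearson
  correlation computed over ~13 bins; the dwell floor removes this
  counting-noise pathology while the full curve (all bins) is still
  reported.

The null model for AHV and speed scores is the **spike-time shift**:
each permutation circularly shifts the entire train by a uniform draw
from (20 s, T − 20 s) and recomputes the statistic, preserving the
train's autostructure while breaking its alignment with behaviour. A
cell is AHV tuned when either side's score exceeds the 95th percentile
of the null distribution of the cell's AHV score, where the null draw
for each shuffle is the **maximum of the right- and left-turn scores**.
Thresholding each side against its own 95th percentile would give the
two-sided label a null exceedance of about 1 − 0.95² ≈ 9.8%; the
max-statistic null calibrates the cell-level test at 5% while the
per-side percentiles are still reported. The same rule is used for the
CW/CCW rotation-velocity test. Speed tuning is a single two-sided score
(negative correlations are genuine negative speed tuning and are
labelled with their sign).

Head-direction classification is conjunctive and deliberately stricter:
in **both** epochs the binned rate distribution must be non-uniform
(occupancy-weighted Rayleigh test, p < 0.01, using the spike count of
the epoch as the effective n in the Zar approximation) and the mean
Rayleigh vector length must exceed the 99th percentile of a **pooled
population null** (shift nulls pooled over all recorded units), with
frames below a 1.5 cm/s speed floor excluded. With two light epochs
unavailable in single-session synthetic data, the two halves of the
session serve as epochs and the result records `epochSource =
"halves"`. The 99th-percentile threshold is data-dependent; on
synthetic Poisson units it is far below the published in-vivo value
because simulated trains lack slow rate fluctuations.

The theta index processes the ±500 ms autocorrelogram (1-ms bins): the
zero-lag peak is equalised to the largest remaining bin, the mean is
subtracted, the squared FFT magnitude is taken after zero-padding to
2^16 samples, the spectrum is smoothed with a 2-Hz mean window, and the
index is the 5–11 Hz peak over the mean power below 50 Hz (theta
modulated when ≥ 5).

# Cross-session unit matching

Candidates for each Fix unit are Free units whose peak channel lies
within 40 µm vertically (50 µm for the 4-neighbour probe layout) and
whose whole-session mean rate differs by at most a factor of 20. Three
similarity categories are combined as `(1/9)·‖local‖₂ + (4/9)·‖global‖₂
+ (4/9)·‖isi‖₂`:

* *Local*: proportional differences `F(x, y) = max(0, 1 − |(x − y)/x|)`
  of the second-peak amplitude, trough-to-peak duration, trough-to-peak
  amplitude and peak-to-trough amplitude (with `F(0, 0) = 1`,
  `F(0, y≠0) = 0` by convention).
* *Global*: amplitude-histogram intersection (3-µV bins) and three
  DTW-based metrics. DTW is exact dynamic programming with a
  Sakoe–Chiba band (default radius 3 samples) on the 4-ms, 30-kHz
  peak-channel window (121 samples, trough at sample 49; waveforms
  recorded at other rates are resampled). The alignment is computed on
  **amplitude-normalised** shapes so that a pure gain change does not
  distort the path; metrics are then evaluated on the original signals
  along that path. Inside the norm, the waveform difference enters as
  `1 − min(d, 1)`, the DTW scale factor as `min(s, 1/s)` (penalising
  both over- and under-warping) and correlations are clipped at zero,
  making "larger = more similar" uniform across components. The
  waveform difference is normalised by the **Fix** peak-to-trough
  amplitude (switchable).
* *ISI*: Pearson correlation and intersection ratio of
  relative-frequency ISI histograms on 50 log-spaced bins from 1 ms to
  10 s — log spacing because ISI structure is scale-free.

The best-scoring candidate is each Fix unit's potential match; a Free
unit claimed by several Fix units goes to the highest-scoring claimant
(the others are recorded as conflicts, not reassigned). Acceptance is
applied last, on raw metric values: ISI correlation > 0.7, all four
local features > 0.7, waveform correlation > 0.95, waveform difference
< 0.3.

# Rotation analysis

The passive stimulus is one full position sinusoid (default 90°
amplitude, 7-s period) flanked by half-sinusoid ramps of the same
period that take the platform from rest to the sinusoid's starting
extreme and back, so the profile starts and ends at rest and has zero
net displacement. Peak position is ±90° and peak speed 2π·90/7 ≈
80.8 °/s, reached during the main sinusoid. The stimulus moves in its
labelled direction only during the main sinusoid's first half-cycle,
so direction-discrimination analyses (direction ROC, direction
decoding, evoked direction selectivity) use the 3.5-s window starting
at the ramp/main boundary, or its first 500 ms.

Velocity tuning uses 5°/s bins of signed velocity with dwell times from
the profile; the null shuffles rates across bins (a bin-shuffle, not a
spike shift, because trial structure rather than autocorrelation is the
confound here). The evoked-response test is a paired Wilcoxon
signed-rank between trial rates during rotation and during the
preceding stationary window of equal duration, and the rotation
modulation index is `|R̄rot − R̄base| / R̄base` (undefined and flagged
at zero baseline; scale-invariant by construction). Active (6°/s) and
passive (5°/s) curves are compared after linearly interpolating the
active curve onto the passive bin centres within the overlapping range
(nearest-bin matching is available as a switch).

Pupil analysis detects rapid eye movements as runs where the
median-filtered (50 ms), outlier-cleaned (|v| > 20 mm/s removed),
lowess-detrended (span 0.01) velocity of horizontal pupil position
exceeds 2.5 SD; a unit is eye-movement modulated when its per-event
rate (−75 to +250 ms windows) correlates significantly with event
amplitude in either direction. The printed outlier unit assumes
millimetre-calibrated traces; the threshold is exposed as a parameter.

# ROC and population decoding

AUCs use the mid-rank (Mann–Whitney) convention for ties; confidence
intervals use the DeLong variance (via pROC) at the 99% level, and AUCs
below 0.5 are rectified to 1 − AUC with the CI reoriented accordingly.
A comparison is significant when the rectified CI lower bound exceeds
0.5. When every rate is tied the CI is degenerate and flagged, never
significant.

The LDA decoder z-scores each neuron with training-fold statistics and
regularises the pooled within-class covariance by analytic
Ledoit–Wolf shrinkage toward the average-variance identity (the
shrinkage intensity is estimated from the training fold, not tuned).
Cross-validation is balanced: each fold holds out exactly one trial per
class, reproducing 54/6 splits for six 10-trial classes and 18/2 for
two. Pseudo-populations draw units with replacement and permute trial
order independently per unit within each stimulus class, so label
marginals are exact by construction; decoding on all six
stimulus × condition classes is a single multiclass problem (parallel
binary decoders are a switch). Bootstrap population-size curves report
mean accuracy and bootstrap IQR per size.

# Connectivity

Cross-correlograms count B-spike lags around each A spike in 0.5-ms
bins over ±50 ms. The published smoothing cut-off for the baseline
(5 kHz) exceeds the Nyquist frequency of a 0.5-ms-binned histogram
(1 kHz) and cannot be taken literally; the baseline is therefore a
gentle Fourier low-pass keeping the lowest harmonics (default 5) of the
CCG. Before fitting, the centre region up to ±4 ms — the zero-lag
shoulder **and** the candidate monosynaptic window itself — is replaced
by interpolation, so a genuine peak or trough cannot inflate its own
baseline (a single-bin transmission peak otherwise leaks into the
smooth baseline and masks itself). Confidence bands are per-bin Poisson
quantiles at the 0.0001 and 99.9999 percentiles; within 1.5–4 ms after
zero, ≥ 2 bins above the band ⇒ excitatory, ≥ 3 bins below ⇒
inhibitory (bins may be non-contiguous; a contiguity switch exists).
Cell types come from k-means (k = 2) on standardised second-peak ratio
and trough-to-peak duration, with the shorter-duration cluster named
"narrow" so labels are independent of initialisation.

# Behaviour

The go/no-go stimulus is a symmetric smooth velocity bump of fixed
32.2-s duration peaking at 16.1 s, with the width chosen so stimuli
with different peak speeds share onset, offset and integrated
displacement. Licking in ≥ 2 of the 250-ms bins after the peak is an
S+ response; block accuracy is the mean of percent-correct S+ and S−
trials over 10 + 10 pseudo-randomly ordered trials. Psychometric curves
are 4-parameter logistics with the floor bounded at 50% (chance for
this design), fitted by Levenberg–Marquardt least squares; the
threshold is the midpoint. Training progression requires ≥ 80% mean
accuracy over 5 consecutive blocks and ≥ 20 blocks. Lesion assessment
quantifies signed turn angles from three consecutive body-centroid
frames with a displacement floor against tracking jitter.

# The synthetic-data generators

Each analysis stage has a generator with known ground truth:

* **Trajectory**: AHV follows a mean-reverting Ornstein–Uhlenbeck
  process (stationary SD 40 °/s, relaxation 0.5 s — giving mostly
  ±80 °/s excursions, as the analysis assumes) integrated into heading;
  speed is a clipped OU process (mean 8, SD 4 cm/s); the body walks in
  the heading direction inside a 92-cm arena; ears sit at fixed
  perpendicular offsets. The smoothness matches the 50-ms filtering
  assumption. Real mice decouple body heading from movement direction,
  pause, groom and rear; none of that is modelled.
* **Spikes**: inhomogeneous Poisson thinning of
  `max(0, baseline + gR·max(AHV,0) + gL·max(−AHV,0) + gS·speed)` times
  a unit-mean von Mises heading term, with a dead-time refractory.
  Rates above 500 Hz abort as unphysiological.
* **Rotation sessions** interleave condition × direction trials
  pseudo-randomly with stationary gaps of 15–30 s (within the protocol's
  10–30 s range but long enough that every trial has a full-length
  baseline window); per-condition speed and direction gains let the
  vestibular+visual condition exceed the vestibular one.
* **Waveform libraries** pair Fix units (biphasic templates with 60–150
  µV troughs, 250–750 µs trough-to-peak, gamma-ISI trains) with
  jittered Free copies on neighbouring channels; distractors are drawn
  with trough-to-peak durations at least 35% away from every Fix unit,
  i.e. physiologically distinct shapes. Default jitters (5% amplitude,
  2% shape, 5% ISI, one channel) emulate a stable chronic recording a
  few hours apart — the "moderate jitter" condition.
* **Coupled pairs** add, for each A spike with probability p, a B spike
  at the synaptic delay (with 0.2-ms jitter); the inhibitory variant
  deletes B spikes in a window after A spikes.
* **Go/no-go observers** respond with a logistic psychometric function
  of the peak-speed difference (threshold/slope/lapse); slope 0 gives a
  step (perfect) observer.

Passing tests on these generators shows the estimators recover known
parameters under the stated noise models; it does not certify
behaviour on real data with non-Poisson firing, drift, or tracking
artifacts beyond the modelled likelihood dropouts.

# Problem sizes and reproducibility

The test-suite and acceptance-script problem sizes are chosen to give
stable statistics at interactive runtimes: 20-minute sessions for
calibration and slope recovery (200 and 50 units, with 200-permutation
nulls standing in for the 1000-permutation analysis default), 5 seeds ×
(20 pairs + 20
distractors) for matching, 1000 null simulations for CI coverage, a
120-unit pool for the 100-neuron decoding check, and 50 independent
pairs for CCG specificity. Every stochastic step takes an explicit
seed, and `runPipeline()` is a pure function of (config, seed) —
unknown configuration keys are fatal so typos cannot silently fall back
to defaults.

# Known limitations

* Conjunctive GLM tuning models, 3-D posture, VOR gain, time-resolved
  ROC traces and jitter-corrected CCG methods are out of scope.
* The Rayleigh p-value uses the Zar large-n approximation with spike
  counts as n, which is anti-conservative for very low-rate cells; the
  conjunctive HD criteria make this harmless in practice.
* The amplitude-drift and atypical-waveform curation rules require raw
  recordings and are exposed only as manual flags.
* Binned-curve correlation is the default score domain; frame-wise
  correlation is available as a switch and gives systematically lower
  scores on the same data.
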