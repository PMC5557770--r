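---
title: "Characterizing the pre-freezing-of-gait phase: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing the pre-freezing-of-gait phase: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prefog)
```

## The problem

Freezing of gait (FOG) is a brief, episodic arrest of forward stepping that
affects many people with advanced Parkinson's disease. Under the threshold
model of FOG, gait degrades progressively in the seconds before an episode
and the freeze triggers once degradation crosses a critical level. If that
degradation is measurable from body-worn inertial sensors, FOG becomes
*predictable* — a cue (e.g. rhythmic auditory stimulation) could be delivered
just before the freeze rather than after it.

`prefog` implements the full analysis chain for testing this hypothesis on
synchronized tri-axial accelerometer and gyroscope streams from three
sensors (left ankle, right ankle, lower back) sampled at 128 Hz, with
clinician-style FOG onset/termination annotations:

1. **Segmentation** of each recording into 2-s *pre-FOG* windows (the 2 s
   ending at each FOG onset) and non-overlapping 2-s *gait* windows, with a
   sufficient-motion check.
2. **Eight features** per window quantifying turning, bilateral symmetry,
   movement amplitude and frequency content.
3. **Paired statistics**: per-(subject, condition) gait vs pre-FOG means,
   paired t-tests, Benjamini–Yekutieli (BY) correction across the
   eight-feature family.
4. **Classification**: a three-feature linear discriminant model scoring the
   probability that a window is pre-FOG, evaluated leave-one-subject-out
   (LOSO) with ROC/AUC and Youden-optimal operating points.
5. A **synthetic-data generator** that emulates the structure of such
   multi-condition cohort recordings, so every stage is testable end to end.

## Segmentation

Pre-FOG candidates cover `[onset - 2 s, onset)`. A candidate is discarded
when an earlier FOG episode intrudes into its support (the phase of interest
is gait *before* freezing, not freezing itself), or when it fails the motion
check. FOG intervals and *all* candidate supports — kept or discarded — are
then removed, and each remaining continuous portion of at least 2 s is tiled
with non-overlapping 2-s windows, trimming equal slack from both ends.

Numerical conventions, fixed so results are reproducible:

* All times convert to 0-based, half-open sample intervals by
  `floor(t * rate)`; seconds appear only at I/O boundaries. Flooring is
  conservative: it never pulls a post-onset sample into a pre-FOG window.
* "More than 50% motionless" is read strictly: a window with exactly half
  its samples motionless still counts as sufficient motion.
* An odd trim splits as `floor(trim/2)` at the start, remainder at the end.
* Candidates whose 2-s support would precede the start of the recording are
  dropped (a degenerate-input guard; within a protocol, walking precedes
  any analyzable FOG).
* Discarded candidates are *excluded* from the gait pool rather than
  returned to it, keeping gait windows uncontaminated by near-FOG data.

A sample is *motionless* when both ankle angular-velocity norms are below
0.5 rad/s **and** the lower-back acceleration norm is within ±10% of a
reference estimated by averaging the norm over a known still interval at the
start of the protocol (near gravity, 9.81 m/s²). The segmentation is tested
for exact equivalence against a brute-force per-sample labeler on randomized
timelines.

## The eight features

| feature | signal | units |
|---|---|---|
| turning degrees | lower-back vertical angular velocity | deg |
| left–right cross-correlation | ankle ML angular velocities | (rad/s)² |
| left–right average SD | ankle ML angular velocities | rad/s |
| left–right SD difference | ankle ML angular velocities | rad/s |
| lower-back SD | lower-back AP acceleration | m/s² |
| locomotor-band power (0.5–3 Hz) | ankle AP accelerations, L/R mean | (m/s²)² |
| freezing-band power (3–8 Hz) | ankle AP accelerations, L/R mean | (m/s²)² |
| freezing index | freezing/locomotor power ratio, L/R mean | — |

Choices the feature definitions leave open, resolved here as package
defaults:

* **Turning degrees**: the angular velocity is low-pass filtered at 1.5 Hz
  with a 4th-order Butterworth applied forward–backward (zero phase, so the
  filter delay cannot bias the integral), integrated by the trapezoid rule,
  and reported as a magnitude — turn direction is arbitrary. Odd-reflection
  padding of about three filter time constants suppresses the edge
  transients of forward–backward filtering on short windows.
* **Cross-correlation**: signals are linearly detrended; the unbiased
  estimator `sum(x_t y_{t+k}) / (N - |k|)` is maximized over lags 0.25–1.25 s
  in *both* directions, since leg leadership is arbitrary. The value is a
  covariance, not normalized to [-1, 1]: it deliberately senses amplitude
  as well as phase alternation.
* **Spectral estimator**: rectangular-window periodogram of the mean-removed
  256-sample window (0.5 Hz resolution). Band edges are half-open
  `[f1, f2)` so the shared 3 Hz edge belongs to the freezing band only; a
  band ending exactly at Nyquist is closed there. The estimator conserves
  power (Parseval) to 1e-9 relative, which the tests assert.
* **Freezing index**: mean of the two per-ankle ratios (not the ratio of
  means). The locomotor power is floored at 1e-8 (m/s²)² and the ratio
  capped at 1e4; motionless windows never reach the features in the normal
  flow, so the guard only totalizes degenerate inputs.
* **SD** uses the sample (n-1) form — immaterial at n = 256 but fixed so
  implementations agree to machine precision.

## Paired statistics

Within each (subject, condition) that has at least one gait *and* one
pre-FOG window, feature values are averaged per class, producing one paired
observation; this absorbs the large gait/pre-FOG imbalance and keeps
conditions of different difficulty comparable. Two-sided paired t-tests are
used (both shift directions occur among the features), and BY correction is
applied across exactly the eight-feature family — the family size is part of
the procedure, so partial families are refused. Zero-variance difference
vectors yield NA rather than a coerced 0 or 1. Significance is decided on
BY-adjusted p ≤ α (equivalent to the threshold-sequence form and easier to
report).

## Classification

Features enter the classifier in ascending order of their paired-test
p-value, skipping any candidate whose absolute correlation with an
already-selected feature exceeds 0.9 (computed on the gait-window pool):
collinear features add nothing to a linear model and destabilize the pooled
covariance. Three features are selected.

The model is a two-class Gaussian discriminant with shared pooled
covariance, ridge-regularized by `1e-6 * trace/d` on the diagonal. Priors
default to the empirical training frequencies (`"equal"` is available);
features are not standardized, since LDA posteriors are affine-equivariant
(a property the tests verify numerically). Evaluation is leave-one-subject-
out. The per-subject Youden-optimal threshold is computed on the held-out
subject's own scores: it characterizes that subject's attainable operating
point — an estimate of the individual critical degradation level — and is an
evaluation statistic, *not* a deployable decision rule. Thresholds are
searched over midpoints of consecutive distinct scores with
"pre-FOG if score > threshold"; J-ties break toward higher specificity,
then the higher threshold (deterministic and conservative about false
alarms). AUC is computed in the rank (Mann–Whitney) form with ties counted
half, which equals the trapezoidal area under the empirical ROC curve.

## The synthetic cohort generator

Real FOG-provoking protocol data are not redistributable, so the generator
emulates their statistical structure: per-subject, per-condition recordings
containing an initial still calibration interval, walking with ~1 Hz stride
/ ~2 Hz step locomotor content, programmed turns (a raised-cosine vertical
angular-velocity bump integrating exactly to the requested angle), FOG
episodes, and — before each non-abrupt FOG — a linear degradation ramp in
which swing amplitude decays, left–right phase asymmetry grows, 3–8 Hz
trembling rises, and a slow turn builds up (turning being a common FOG
trigger).

The signal model is a sum of harmonics with per-segment envelopes plus
Gaussian sensor noise, *not* a biomechanical simulation: the eight features
only sense amplitude, phase and band content, so harmonic placement is the
property that matters, and it is asserted spectrally in the tests. Gravity
enters as a constant 9.81 m/s² on the vertical accelerometer axes so the
±10% norm check is exercised realistically. The degradation ramp is linear —
the simplest shape consistent with a threshold model. Default degradation
(amplitude decay to 0.5, 0.8 rad phase jitter, 1 m/s² trembling at 5 Hz,
1.2 rad/s pre-FOG turn rate) was chosen once as a moderate, detectable
effect; no quantitative per-feature effect sizes are published for real
pre-FOG data, so these are free parameters of the generator, not empirical
values.

Randomness derives from a single master seed; per-(subject, condition)
streams use seeds derived by token hashing, making cohorts reproducible yet
effectively independent across recordings. Subjects get mildly jittered gait
parameters (±15% amplitudes, stride rate) so leave-one-subject-out is a
genuine generalization test.

Two stock scenarios define the package's study conditions:

* `default_scenario()`: 10 subjects × 5 conditions, two FOG episodes per
  condition (~50 paired samples per cohort — the scale of a realistic
  multi-condition FOG protocol, at desk-friendly runtime).
* `null_scenario()`: degradation disabled and turns removed. One subtlety
  matters here: gait windows that straddle the still→walk boundary pass the
  motion check (≥50% moving samples) yet contain flat stretches, biasing
  gait means low even under "no degradation". The null scenario therefore
  separates the calibration stillness from the walking data with an abrupt
  FOG, so every gait window is pure walking and gait vs pre-FOG windows are
  exchangeable under the null. With this construction the family-wise
  BY-corrected type-I error over 200 simulated cohorts stays within the
  binomial band around α = 0.05 (asserted in the acceptance tests).

**What passing tests do and do not show.** The generator reproduces the
*structure* the analysis assumes — band placement, antiphase swing,
annotated episodes, a monotone pre-FOG ramp. It does not reproduce
biomechanical waveforms, stride-to-stride variability structure,
sensor-mounting artifacts, or the heterogeneity of real FOG phenotypes.
Recovery results on synthetic cohorts (e.g. LOSO AUC near 1 under strong
programmed degradation) validate the pipeline's correctness, not clinical
performance; published results on real cohorts are markedly lower (mean
AUC ≈ 0.76), as expected with subtle real-world effects.

## Problem sizes and runtime

Simulation-based checks use cohort sizes chosen to give stable Monte-Carlo
estimates at interactive runtimes: 200 six-subject null cohorts for the
type-I error, 50 ten-subject cohorts for effect-direction power, 100
randomized ≤ 60 s timelines for the segmentation oracle, and an
11-subject cohort for classifier recovery. The full suite runs in a few
minutes on one CPU.

## Known limitations

* Windows are non-overlapping, as in the reference workflow; a real-time
  predictor would use sliding windows and incur correlated scores.
* Start-hesitation FOG (episodes after inactivity) is out of scope; the
  annotation producer is responsible for excluding it.
* Voluntary stops are not modeled, so specificity against deliberate
  stopping cannot be assessed from these simulations.
* The per-subject Youden threshold uses test-subject scores (see above) and
  must not be read as deployable performance.
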