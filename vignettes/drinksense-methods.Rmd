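---
title: "Fluid-intake assessment from inertial sensors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fluid-intake assessment from inertial sensors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Adequate hydration is hard to self-monitor, and two families of
inertial-sensor solutions compete for the job: a wrist-worn IMU, which sees
every arm movement of a drinking gesture, and a "smart container" with an
IMU fixed to the cup's bottom, which only moves while the cup is in use.
`drinksense` implements a hierarchical assessment pipeline that works for
both placements:

1. **Gesture recognition** — sliding-window statistical features and an
   RBF-kernel SVM label each fragment of the stream as one of the five
   phases of a drinking event (*grasp*, *pre-sip*, *sip*, *post-sip*,
   *release*; the container arm only ever moves during
   *pre-sip*..*post-sip* and is classified over those three), followed by
   a run-length correction of isolated misclassified fragments.
2. **Volume estimation** — duration and inclination features of the
   recognized *sip* segment feed support vector regression (SVR) models
   that estimate the mass of water taken, optionally aided by a fill-level
   estimate regressed from the *pre-sip*..*post-sip* span.

Everything is evaluated by leave-one-subject-out (LOSO) cross-validation,
so reported performance is always on an unseen participant.

## The synthetic session generator

The human study this pipeline targets is a 12-participant protocol — 7
fill levels (100–400 g in 50 g steps in a 500 g cup) x 3 instructed sip
sizes x 4 repetitions, i.e. 84 events per participant and 1008 in total,
recorded at 128 Hz with ±16 g / ±2000 deg/s sensors — whose recordings are
not publicly available.  `generate_dataset()` therefore synthesizes
sessions with the statistical and physical structure the analysis relies
on, and the package's empirical claims are claims about this synthetic
population:

* **Sip amounts** are truncated normals per category (large 53.82 ± 8.58 g,
  medium 27.23 ± 6.20 g, small 10.71 ± 5.56 g; floor 1 g, capped at the
  fill level, redrawn on violation).
* **Sip duration** is `speed_p * (1 + amount / rate_cat)` seconds.  The
  per-participant speed factor `speed_p ~ U(0.85, 1.15)` makes LOSO
  genuinely harder than random splits.  The flow rate
  `rate_cat = 4 + 0.22 * mean_cat` g/s grows with the category's mean
  amount: people drain a large instructed sip faster than they nurse a
  small one.  This category dependence is deliberate — if one global
  amount–duration law held, a single general regressor would extract all
  available signal and sip-size-dependent models could never help, which
  would contradict the qualitative behaviour the pipeline is designed to
  expose.  Duration is strictly increasing in the drawn amount within a
  participant and category.
* **Container tilt** during the sip peaks at
  `35 + 55 * (1 - fill/capacity)` degrees (plus 3° of event-to-event
  noise): an emptier cup must be tipped further.  This is the physical
  coupling that makes fill-level regression possible at all.
* **Phase durations** other than the sip are uniform draws (grasp/release
  0.5–1.5 s, pre-/post-sip 1–2 s); no published durations exist for these
  gestures, so these are stated defaults chosen to look like unhurried
  table-top drinking.
* **Placement asymmetry.**  The container signal is the tilt trajectory
  rendered into gravity (accelerometer) and tilt rate (gyroscope) with
  0.02 g / 1.5 deg/s sensor noise; it is exactly stationary outside
  *pre-sip*..*post-sip*.  The wrist sees the same tilt plus a constant
  per-participant roll offset (±15°), a reach-yaw ramp during *grasp* and
  *release*, a small vertical acceleration bump while lifting and putting
  down, and **3x the container's noise** — implementing the observation
  that wrist signals carry much greater inter-subject variability.
  Gravity convention: container +Z up when the cup rests on the table;
  tilt rotates gravity into Y.

What the generator does **not** emulate: biomechanically realistic arm
kinematics, liquid sloshing, swallowing micro-pauses, or confounder
activities (eating, typing).  Passing tests on this population therefore
show that the pipeline's machinery is correct and that its comparative
conclusions follow from the stated couplings — not that the absolute
accuracies transfer to free-living data.

## Signal processing choices

* **Derived channels.**  Angular acceleration is the central finite
  difference of angular velocity (one-sided at the ends).  "Inclination"
  is computed per axis as the angle between the instantaneous
  acceleration vector and that axis, `acos(a_i/||a||)` in degrees — no
  orientation filter is used, so the feature works from raw channels
  alone; during a slow sip the acceleration is gravity-dominated and the
  z-inclination tracks the cup's tilt.  A zero-norm acceleration maps to
  90° per axis.  Whether tilt should be one scalar or three per-axis
  angles is genuinely open; the per-axis choice is isolated behind
  `derive_channels()`.
* **Windowing.**  The study grid crosses window sizes
  {16, 24, 32, 40, 48, 56} samples with overlaps {25, 50, 75, 87.5} %;
  every combination yields an integer step.  Trailing partial windows are
  dropped, not padded.  A window's ground-truth label is the majority of
  its per-sample labels, ties broken toward the label whose run starts
  earlier — a convention, since no assignment rule is standard.
* **Gesture features.**  8 statistics (mean, SD, variance, max, min,
  range, skewness, kurtosis) x 4 channel groups (acceleration, angular
  velocity, angular acceleration, inclination) x 3 axes = 96 features.
  Skewness and kurtosis are population moment ratios; kurtosis is
  non-excess (Gaussian ≈ 3); zero-variance windows map both to 0 rather
  than NaN.

## Classification and postprocessing

The gesture classifier is an RBF-kernel SVM (one-vs-one multiclass, class
order grasp < pre-sip < sip < post-sip < release).  Hyperparameters are
fixed, not tuned per fold: C = 1 and kernel width
`1/(n_features x mean feature variance)` on standardized features, with
standardization statistics always fitted on the training fold only.
Training folds larger than 2500 windows are reduced by a deterministic
stratified subsample (evenly spaced within each class) before fitting;
this keeps the quadratic-programming cost bounded at full protocol scale
while preserving class proportions.

The postprocessing rule rewrites any run of one or two consecutive
fragments that disagrees with its surroundings, provided the preceding and
following fragments agree, to the preceding fragment's label.  The scan is
sequential left-to-right with corrections immediately visible, so a
correction can enable a later one (the alternative — a single simultaneous
pass — is weaker and was rejected; the rule is isolated behind
`postprocess_labels()`, which is idempotent).  Fragments at the sequence
boundaries are never modified.

Window-label runs are mapped back to sample intervals by the midpoint
convention: the boundary between two runs falls halfway between the
midpoints of the straddling windows.  If several *sip* runs survive
postprocessing, the longest is kept; events with no recognized sip are
excluded from volume estimation and reported as a count.

## Regression

* **Features** (from the *sip* interval for volume, from the recognized
  *pre-sip*..*post-sip* span for fill level): duration; per-direction
  average, maximum and integral of inclination (trapezoidal rule extended
  half a sample at each end, so a constant integrates to value x
  duration); counts of samples above 10°–90° thresholds; counts of
  samples above 10–90 % of the interval's own per-direction maximum
  (interval-local normalization keeps the feature self-contained; a zero
  maximum yields zero counts).  Counts are raw sample counts, not
  durations.  With the fill level appended the vector has 65 entries,
  without it 64.
* **Models.**  Epsilon-SVR with linear and Gaussian kernels, C = 10,
  epsilon = 1 g, features standardized per training fold, targets left in
  grams.  Fill-level estimation never sees the fill-level feature.
  Sip-size-dependent volume estimation trains one SVR per category and
  routes each test event by its ground-truth category (how a deployed
  system would obtain the category — e.g. from a sip-size classifier — is
  out of scope and flagged here); the general model ignores the category.
* **Combination study.**  Volume estimation is crossed over {true,
  recognized} sip segments x {no fill, fill} per arm, with the fill-level
  source being the true value for true segments and the LOSO-estimated
  value for recognized segments, using the general linear-kernel SVR.
  Fill-level features are computed on recognized spans (the end-to-end
  condition); the container arm's windows are restricted to its motion
  span using the event's annotated boundaries, mirroring the manual
  extraction of drinking activities that precedes classification.

## Problem sizes and determinism

The package's own studies run at the full protocol scale (1008 events,
LOSO over 12 participants) for the headline numbers; unit and property
tests use reduced grids (3 participants x 3 fills x 2 repetitions) chosen
to exercise every code path at interactive speed.  The qualitative
comparisons (sip-size-dependent vs general, wrist vs container, true vs
recognized, postprocessing gains) are asserted as majority-of-seeds
properties over five full-scale runs.  All randomness flows from the
single protocol seed through R's RNG; identical seeds give byte-identical
serialized datasets.

## Known limitations

* Absolute error levels depend on the generator's noise scales and are
  not calibrated against any human recordings; only directions and orders
  of magnitude are meaningful.
* Raw-classification accuracy on the synthetic population is high, so the
  postprocessing gain, while consistently larger for the wrist arm, is
  small in absolute terms.
* Ground-truth sip-size dispatch overstates what a deployed
  sip-size-dependent model could achieve.
* The container arm is evaluated only on its motion span; a fielded smart
  container would also need a (nearly trivial) motion detector.
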