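---
title: "Inertial rowing motion capture: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inertial rowing motion capture: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rowimu)
```

This vignette documents the models implemented in `rowimu`, the tunable
parameters and their defaults, the numerical choices made where the design
was genuinely open, and what the built-in simulator does and does not
emulate. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## Coordinate systems and quaternion conventions

Three frames are used. The ground frame (GCS) is East-North-Up: +X east,
+Y north, +Z up. The sensor frame (SCS) is the native frame of each IMU
node. The body frame (BCS) of a segment coincides with the GCS during the
initial standing pose, which is what makes mounting calibration possible
without a magnetic-north-aligned rig.

Orientations are unit quaternions, scalar first, Hamilton (right-handed)
product, mapping SCS into GCS by the sandwich product `q ⊗ [0, v] ⊗ q*`.
Since `q` and `−q` are the same rotation, single-quaternion estimation
routines canonicalise the sign (`q0 ≥ 0`), while orientation *series*
enforce sign continuity sample-to-sample so that componentwise
interpolation is well defined.

## Magnetometer calibration

Hard iron adds a constant offset to every reading; soft iron multiplies the
field by a (symmetric, near-identity) matrix. Rotating the node through
varied attitudes places the readings on an ellipsoid; `fit_mag_calibration()`
fits the general quadric `xᵀAx + bᵀx + c = 0` in the total-least-squares
sense (smallest singular vector of the design matrix, after centring and
scaling for conditioning) and extracts:

* hard iron: the ellipsoid centre `−A⁻¹b/2`;
* soft-iron correction: the unique symmetric positive-definite square root
  of `A`, normalised to unit determinant. The SPD choice removes the
  rotational ambiguity of ellipsoid-to-sphere maps; the unit-determinant
  normalisation makes the correction volume-preserving, leaving the field
  *magnitude* to be reported separately as the mean corrected radius.

A `"sphere"` mode (hard iron + single scale) is available since soft iron
is often negligible; the full ellipsoid fit is the default. The fit is
algebraic and deterministic - no seed, no iteration. Degenerate coverage
(e.g. rotations about a single axis, which is all a rowing stroke itself
provides) leaves more than one near-null singular direction and is rejected
with an error; calibration therefore requires a dedicated waving
acquisition, which the simulator provides via `simulate_mag_samples()`.

## The orientation filter

Each step first propagates the quaternion with the gyroscope rate,
`q̇ = ½ q ⊗ [0, ω]`, then corrects along the negative gradient of the
combined measurement objective. For one reference field `p_G` (unit vector
in GCS) observed as `p_S` (unit vector in SCS), the residual is the vector
part of `q* ⊗ [0, p_G] ⊗ q − [0, p_S]`, and the gradient is `Jᵀf` with the
3×4 Jacobian taken of the raw bilinear sandwich (no renormalisation inside
the derivative, so `fusion_gradient()` is exactly the derivative of
`½‖f‖²` and is verified against central finite differences). Gravity and
the magnetic field contribute additively.

**Step-size safeguard.** The correction applied is

    ξ · ∇f / max(‖∇f‖, 1),

i.e. a fixed-length normalised step of size ξ when the gradient is large
(fast reconvergence after initialisation transients) and a plain
proportional gradient step near the minimum. A *purely* normalised step
cannot settle: it oscillates around the minimum with amplitude ≈ ξ, which
at the default ξ = 0.1 would be ~11° of orientation error. The damped form
makes static descent monotone with an exact fixed point at the true
orientation, which the test suite asserts directly.

Parameters and defaults:

* `xi = 0.1` (dimensionless, per step). This is a deliberately aggressive
  correction gain: static convergence from a 30° error reaches < 0.5°
  within a few tens of steps. The cost is sensitivity to the
  linear-acceleration confound (below). Configurable per call.
* `init_window = 2` s: the quasi-static standing interval averaged for the
  initial orientation (`quat_from_accel_mag()`, a TRIAD construction) and
  for the magnetic reference. The magnetic reference is taken as the
  initial-orientation image of the mean measured field, projected exactly
  into the North-Up plane - so no dip angle needs to be assumed, and yaw
  is unbiased by construction.
* `dt` is taken per sample from the log timestamps, not assumed constant.

Known limitation: the accelerometer is used as a pure gravity observation.
During the propulsion sweep the sensor point accelerates at several m/s²,
tilting the apparent gravity by 10-20°; with the default gain this leaks
into orientation at the few-degree level. The simulator exposes exactly
this approximation through its `linear_accel` flag, and the package's
round-trip accuracy checks quantify the filter both without the confound
(isolating estimator correctness) and with sensor noise.

## Skeleton, alignment and joint angles

The default body model has 17 rigid segments (head, torso, pelvis,
2 clavicles, 2 × upper arm / forearm / hand, 2 × thigh / shank / foot),
with lengths as standard anthropometric fractions of standing height and a
reduced upper-limb model for arm-dominated analyses. Forward kinematics
iterates breadth-first from the pelvis at the origin; every reconstructed
bone length equals its configured length by construction, which the tests
assert to machine precision.

Mounting calibration uses the standing pose: BCS ≡ GCS there, so
`q_B^S = (q_S,init^G)*`, chordal-averaged over the static window. Segment
orientation then follows as `q_B^G = q_S^G ⊗ q_B^S`. Uninstrumented
segments inherit the nearest instrumented ancestor's orientation.

Joint channels are interior angles at the joint: the angle between the
*reversed* proximal-segment direction and the distal-segment direction,
via arccos of the dot product, clamped to [0, π]. With this convention a
straight elbow reads near π (≈ 3.1 rad) and arms-down standing reads 0 rad
of shoulder flexion, matching the magnitudes customary for on-water elbow
and shoulder statistics. The channel map (which segment pair defines the
shoulder channel, etc.) is data, not code - `default_channel_map()` can be
replaced per call, and no flexion-positive affine remap is applied by
default (the raw arccos value is the stored quantity).

Multi-node synchronisation resamples all orientation streams onto the
coarsest stream's timebase over the overlapping interval, interpolating
quaternion components linearly after sign alignment and renormalising.

## Stroke analytics

Cycle boundaries are shoulder-flexion maxima found by a prominence-filtered
peak picker: topographic prominence ≥ 20% of the signal range, minimum
inter-peak distance 50% of the median inter-peak spacing (both
configurable). Prominence, not height, is what rejects ripple superimposed
near the crest. The detector is offset-invariant.

Stroke metrics follow exact arithmetic: cadence = 60 / mean period
(strokes/min), period SD uses the sample (n−1) convention, and the
propulsion/recovery ratio of a cycle is the ratio of labelled sample
counts inside it. Per-cycle statistics resample each cycle onto a fixed
101-point 0-100% phase axis (the biomechanics convention); ROM ≡ MAX − MIN
per cycle identically. Note the inclusive endpoints of the phase axis
count the boundary peak twice, biasing a cycle's MEAN upward by about
amplitude/101 - negligible for analysis, but visible to exact tests.

Agreement between two angle series reports the OLS slope/intercept,
Pearson correlation, Bland-Altman bias with `bias ± 1.96·SD` limits, and a
relative error in percent. The error normalisation is the reference range
(ROM), not the pointwise reference value, because flexion channels pass
through zero where pointwise relative error is undefined.

## Features and classification

The 33-feature set per channel is: mean, median, SD, median absolute
deviation (about the median), 25th/75th percentiles, IQR, moment skewness,
excess kurtosis, variance, signal entropy, spectral entropy, 3 power-
spectrum features, autocorrelation at lags 1-3, and 15 band-power
features. Where a family is named but not fully specified, the package
fixes it as: `powersp(1-3)` = total power, peak power, peak frequency (Hz);
`acorr(1-3)` = normalised autocorrelation at lags 1-3; `spwf(1-15)` =
relative power in 15 equal-width bands from 0 to Nyquist; signal entropy =
Shannon entropy of a 16-bin amplitude histogram; spectral entropy = Shannon
entropy of the normalised one-sided power spectrum of the demeaned
segment. Constant segments yield zeros (not NaN) for all dispersion,
entropy and spectral features. Spectral features are computed after mean
removal, so they are offset-invariant; windows carry no absolute time.

Two record types share the extractor: 10-sample windows with 5-sample
overlap for propulsion/recovery phase work, and whole strokes
(shoulder-peak to shoulder-peak) for proficiency work - four upper-limb
channels × 33 = 132 columns per record.

NCA feature selection learns one non-negative weight per feature by
maximising the leave-one-out stochastic-neighbour objective with the
diagonal metric `d(i,j) = Σ w_k² |x_ik − x_jk|`, kernel width σ = 1, L2
penalty λ = 1/n by default, by monotone gradient ascent with step halving
and non-negativity clamping. Features with weight > 0.1 are retained. The
optimiser is seeded through its (mildly randomised) initial weights.

Model training: participant-level 75/25 split (no group spans partitions;
a record-level fallback exists behind an explicit flag, because small
cohorts may not have two groups per class), 10% of training records held
out for validation, grid search scored by validation accuracy, refit on
train+validation, final accuracy and trapezoidal AUC on the held-out test
records. Standardisation is fitted on training data only. Default grids
cover SVM (RBF; C ∈ {1…2000}, γ ∈ {10⁻³…10⁻¹}), L2 logistic regression
(C ∈ {0.1…50}, via ridge-penalised GLM), decision tree (depth 2-8) and
XGBoost (10-50 rounds, depth 2-3, η = 0.25, single thread for
determinism). The package's own ROC/AUC implementation is cross-checked
against an independent reference implementation in the test suite.

## The simulator: what it emulates, and what it does not

`simulate_kinematics()` prescribes each joint channel as two half-cosine
arcs per cycle: a fast propulsion sweep from the channel maximum to its
minimum over `propulsion_fraction` of the cycle and a slower recovery
return. The waveform is continuously differentiable (zero slope at the
junctions), periodic, and carries exact phase labels by construction.
Per-cycle period jitter and multiplicative amplitude jitter model
stroke-to-stroke variability. A 2 s static standing interval plus a 1 s
smoothstep ramp precede the first cycle, matching the initialisation
protocol the filter and mounting calibration assume.

Defaults are the study conditions the package targets: 1.72 s stroke
period (jitter SD 0.05 s) with a propulsion fraction near 2/3
(propulsion/recovery ≈ 2), channel means/amplitudes at skilled-rower
elbow/shoulder magnitudes, 100 Hz sampling, gravity 9.81 m/s², magnetic
field 0.5 gauss at 60° dip. The novice stock profile differs in period
(1.71 s), jitter (0.08 s) and a five-fold larger amplitude variability.
Nominal sensor noise levels are gyro 0.01 rad/s, accel 0.05 m/s², mag
0.005 gauss; hard/soft-iron distortion and gyro bias are planted through
the profile. All randomness flows from the single profile seed;
identical seeds give byte-identical streams.

The inverse sensor model differentiates the orientation series by central
differences for the gyroscope, inverse-rotates gravity (plus, optionally,
the second finite difference of the sensor-point position from the
kinematic chain) for the accelerometer, and distorts the inverse-rotated
earth field for the magnetometer.

What the simulator does **not** emulate - and hence what passing tests do
not demonstrate about real recordings: soft-tissue artefact (sensors ride
on muscle, not bone), non-stationary magnetic disturbance near a boat,
gyro bias drift with temperature, sample dropouts and jitter in the
logging chain, out-of-sagittal-plane arm motion (the simulated arm
rotates about the lateral axis only), and genuinely biological
inter-stroke correlation structure. Classification results on simulated
cohorts demonstrate pipeline correctness (separable classes are separated,
null classes are not), not field-level proficiency-recognition accuracy.

## Problem sizes and numerical tolerances

The test suite and acceptance script run on desk-scale problems chosen as
the package's own validation sizes: 10-40 s recordings at 100 Hz with the
6-node upper-limb model, 400-800 calibration samples, cohorts of ~150
stroke records and feature sets of 120-160 records for classifier checks.
Key numerical tolerances asserted: quaternion algebra to 1e-12, analytic
vs finite-difference gradients to 1e-6, noiseless hard-iron recovery to
1e-8, rigid-link lengths to machine precision, noiseless end-to-end
joint-angle recovery to 0.5° RMSE and 3° under nominal noise. The
gyroscope finite-difference identity is checked at 400 Hz, where the
central-difference discretisation error falls below 1e-6.

## Open design choices, resolved

* **Sandwich direction.** The objective conjugates on the left
  (`q* ⊗ p_G ⊗ q` maps GCS references into the SCS for comparison with
  measurements); `q` itself is always SCS→GCS, and every call site
  documents which way it maps.
* **Combined vs per-field normalisation.** The gradient of the two field
  objectives is summed first and the safeguard applied to the combined
  vector.
* **Shoulder channel definition.** Torso axis vs upper-arm axis; the
  mapping is configuration (`default_channel_map()`), not code.
* **Windows in time vs samples.** Window length is specified in samples
  (10/5); at 100 Hz these are 100 ms windows. A milliseconds-based
  reading would conflict with the sample-based definition at any common
  rate, so samples are authoritative and the rate is recorded alongside.
* **Period variability.** The reported SD is the per-stroke sample SD
  within a recording, not the SD of per-trial means.
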