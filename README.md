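# rowimu

Inertial motion capture and stroke-quality analysis for rowing, in R.

Rowing proficiency shows up in the standardisation and repeatability of the
stroke: cadence, stroke-period variability, the propulsion/recovery rhythm,
and the flexion-extension ranges of the shoulder and elbow. `rowimu`
reconstructs these quantities from body-worn 9-DoF inertial measurement
units (triaxial gyroscope + accelerometer + magnetometer) instead of
cameras, so athletes can be analysed on open water. It is aimed at sport
scientists and biomechanics researchers working with wearable sensor logs.

## What it computes

**Orientation fusion.** Each node's orientation is a unit quaternion
`q = q0 + q1 i + q2 j + q3 k` (scalar-first, Hamilton convention) mapping
the sensor frame (SCS) into an East-North-Up ground frame (GCS). The filter
propagates the gyroscope quaternion rate

    q̇ = ½ q ⊗ [0, ω]

and corrects it along the negative gradient of the measurement objective

    f(q, p_G, p_S) = vec(q* ⊗ [0, p_G] ⊗ q) − p_S,       ∇f = Jᵀ f

summed over the two reference fields p_G (gravity and the geomagnetic
field, observed in the sensor frame as p_S), with update

    q(t) = q̂(t−1) − ξ · ∇f / max(‖∇f‖, 1)

followed by renormalisation (ξ = 0.1 per step by default). Magnetometer
readings are first corrected for hard/soft-iron distortion by an algebraic
least-squares ellipsoid fit.

**Skeleton reconstruction.** A rigid 17-segment body tree (pelvis-rooted)
is posed by forward kinematics from the per-segment orientations,
`q_B^G = q_S^G ⊗ q_B^S`, with the mounting quaternion `q_B^S` calibrated
during an initial standing pose. Joint flexion channels (SFl/SFr, EFl/EFr,
knee, foot) are interior angles between adjacent segment directions
(arccos of the dot product, radians in [0, π]).

**Stroke analytics.** Cycles are delimited by shoulder-flexion peaks
(prominence-filtered peak picking); the package reports period mean ± SD,
cadence (60/period), propulsion/recovery ratio from phase labels, and
per-cycle ROM/MAX/MIN/MEAN statistics on a 101-point normalised cycle axis,
plus slope/correlation/relative-error/Bland-Altman agreement against a
reference system.

**Classification.** Sliding windows (10 samples, 5 overlap) or whole
strokes are featurised with the standard 33-feature time/frequency set per
channel (132 features for the four upper-limb channels), optionally reduced
by neighbourhood component analysis (weights > 0.1 retained), and
classified with SVM / logistic regression / decision tree / XGBoost under
grid search, participant-level 75/25 splits with a 10% validation subset,
and trapezoidal ROC/AUC evaluation.

**Simulator.** A built-in rowing-motion generator (asymmetric two-half-
cosine stroke waveforms, per-cycle period and amplitude jitter, exact phase
labels) plus an inverse sensor model (gyro from quaternion differences,
gravity + linear acceleration, distorted magnetometer, sensor noise and
biases) provides ground truth for every stage.

## Worked example

```r
library(rowimu)

profile <- coach_profile(duration = 30, seed = 42)   # 1.72 s stroke, 2:1 rhythm
model   <- upper_body_model(height = 1.75)
truth   <- simulate_kinematics(profile, model)
streams <- imu_from_motion(truth)                    # raw 9-DoF logs per node

cal     <- fit_mag_calibration(simulate_mag_samples(profile, seed = 43))
orients <- lapply(streams, fuse_imu, cal = cal)
static  <- lapply(orients, function(o) o[o$t <= 2, ])
calib   <- calibrate_alignment(static, model)
angles  <- compute_joint_angles(model, orients, calib,
                                channels = default_channel_map()[1:4, ])

events  <- detect_cycles(angles, channel = "SFl")
stroke_metrics(events, phase_labels = truth$phase)
#> <stroke_metrics> 15 cycles
#>   period : 1.747 +/- 0.059 s
#>   cadence: 34.35 strokes/min
#>   propulsion/recovery: 1.97 +/- 0.03
```

The recovered period (1.747 ± 0.059 s) and rhythm (1.97) match the
simulated skilled-rower profile (1.72 s ± 0.05, 2:1 duty cycle) within the
cycle-sampling error of a 30 s recording. Per-cycle joint-angle statistics
and agreement against the ground truth:

```r
tidy(cycle_statistics(angles[, c("t","SFl","SFr","EFl","EFr")], events))
#> # A tibble: 16 × 4  (excerpt)
#>   channel stat   mean      sd
#>   SFr     ROM   2.31  0.0869
#>   SFr     MEAN  1.58  0.0209
#>   EFr     MAX   3.12  0.00891

glance(compare_angle_series(angles$SFr,
         approx(truth$angles$t, truth$angles$SFr, xout = angles$t)$y))
#> slope 1.01, correlation 0.994, mean_error_pct 2.42, bias 0.0007
```

The elbow maxima near 3.1 rad (nearly straight arm) and shoulder means near
1.6 rad are the magnitudes expected for on-water technique; the residual
~2% tracking error is dominated by the linear-acceleration confound of the
accelerometer during the propulsion sweep (the simulator can disable it
with `linear_accel = FALSE` to isolate the filter itself).

`autoplot()` methods produce the standard figures: cycle-statistics
envelopes, Bland-Altman plots, ROC curves, PCA score plots and NCA weight
plots. A command-line front end over the same functions is installed at
`inst/cli/rowimu.R` (subcommands `simulate`, `calibrate-mag`, `fuse`,
`reconstruct`, `strokes`, `compare`, `features`, `run`).

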