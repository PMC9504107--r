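# posturekit

Whole-body posture capture from body-worn 9-axis MARG sensor nodes
(accelerometer + gyroscope + magnetometer), joint-angle reconstruction over
a 15-segment rigid body model, and recognition of seated work tasks from
windowed joint-angle features.

The package is aimed at wearable-biomechanics work where optical motion
capture is impractical: ergonomics and workplace studies, seated-posture
monitoring, and any setting where a handful of inertial nodes must be turned
into interpretable joint kinematics and an activity label.

## What it computes

The pipeline runs in the order a recording session does:

1. **Sensor calibration.** Magnetometer hard-iron offsets and axis scales by
   least-squares fitting of the axis-aligned ellipsoid
   ((Hx−ex)/a)² + ((Hy−ey)/b)² + ((Hz−ez)/c)² = 1 to a wand-wave, mapping
   raw readings onto a sphere of radius R (the field modulus); gyroscope
   bias from the mean rate over an initial still interval.
2. **Static attitude.** Roll/pitch from gravity, yaw from the
   tilt-compensated field: φ = atan2(ay, az), θ = asin(−ax/g),
   ψ = −atan2(hGy, hGx).
3. **Gradient-descent fusion.** A complementary quaternion filter: the
   gyro-driven derivative ½ q⊗(0, ω) corrected by −β ∇f/‖∇f‖, where f
   stacks the gravity and magnetic alignment objectives, integrated per
   frame and normalized.
4. **Skeleton reconstruction.** Body-to-global quaternions per segment
   (qBG = qSG ⊗ qSB\*), pelvis-rooted forward kinematics
   D1 = D0 + q⊗(0, l·û)⊗q\*, and joint flexion angles
   θ = arccos(d⃗V · d⃗W / |d⃗V||d⃗W|) for the breast, waist, shoulder,
   elbow and knee channels.
5. **Features and classification.** 1000 ms windows with 50% overlap, 23
   time/frequency features per joint-angle channel, and evaluation of five
   classifiers (logistic regression, decision tree, RBF SVM, random forest,
   k-NN) with a held-out test split, 10-fold cross-validated model
   selection, weighted precision/recall/F1 and micro-averaged AUC/AUPRC.

A built-in simulator inverts the sensing model (scripted segment motion →
gyro/accel/mag traces with configurable bias, noise and hard iron), so
every stage is testable end to end without recorded data. See the methods
vignette (`vignettes/posture-capture-methods.Rmd`) for the models,
conventions and limitations.

## Worked example

Calibrate a magnetometer from a simulated wand-wave with hard iron
(0.12, −0.05, 0.20) gauss:

```r
library(posturekit)
set.seed(42)
dirs <- matrix(rnorm(1200), ncol = 3); dirs <- dirs / sqrt(rowSums(dirs^2))
truth <- mag_calibration(c(0.12, -0.05, 0.20), c(0.52, 0.47, 0.43), 0.47)
cal <- fit_ellipsoid(invert_mag_calibration(truth, dirs * 0.47))
cal
#> <mag_calibration>
#>   hard-iron offsets (gauss): +0.1200 -0.0500 +0.2000
#>   semi-axes (gauss):          0.5200  0.4700  0.4300
#>   field modulus R (gauss):    0.4719   fit RMS: 8.09e-17
```

The injected offsets and semi-axes come back exactly; the fit RMS is the
residual radial deviation after calibration (floating-point zero here).

Script a seated knee flexion (thigh held at 85°, calf swinging so the knee
angle is 45° − 30°·sin(2π·0.5t)), synthesize MARG traces, fuse, and
reconstruct the knee angle:

```r
script <- motion_script(8, 400, segments = list(
  right_thigh = list(axis = "y", offset = 85, start = 2),
  right_calf  = list(axis = "y", offset = 40, amp = 30, freq = 0.5, start = 2)))
qs <- script_quaternions(script); t <- attr(qs, "t")
tracks <- list()
for (seg in names(qs)) {
  syn <- synthesize_trace(qs[[seg]], t = t, seed = 1)
  trace <- correct_inertial(estimate_inertial_errors(syn$trace, c(0, 1.5)), syn$trace)
  track <- fuse_trace(trace, beta = 0.1)
  tracks[[seg]] <- apply_mounting(track, sensor_to_body(track, c(0, 1.9)))$qBG
}
model <- default_body_model(1.75)
for (seg in setdiff(model$segment, names(tracks))) tracks[[seg]] <- matrix(c(1,0,0,0), 1)
angles <- joint_angle_series(propagate_positions(model, tracks), t = t)
summary(angles$KFr[t > 3.5])
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   14.95   25.97   49.67   47.09   67.82   75.11
```

The reconstructed knee sweeps 15°–75° around 45°, exactly the scripted
waveform, recovered through noisy sensing, bias correction, fusion and
forward kinematics.

Generate the default 4-task dataset (100 windows per class) and evaluate
the classifiers:

```r
task <- generate_task_dataset(n_per_class = 100, seed = 7)
ds <- build_dataset(task$series, task$labels)
evaluate_classifiers(ds, seed = 7)
#> <evaluation_report> 10-fold CV, 344 train / 88 test windows, seed 7
#>               accuracy precision recall     f1 auc  auprc
#> logistic        1.0000    1.0000 1.0000 1.0000   1 1.0000
#> tree            1.0000    1.0000 1.0000 1.0000   1 1.0000
#> svm             1.0000    1.0000 1.0000 1.0000   1 1.0000
#> random_forest   1.0000    1.0000 1.0000 1.0000   1 1.0000
#> knn             0.9886    0.9891 0.9886 0.9886   1 0.9999
```

All five families exceed 95% accuracy on this separable-by-construction
dataset — a property check of the feature/evaluation machinery, not a claim
about recorded participants.

`run_pipeline(run_config())` chains all stages (calibrate → correct →
initialise → fuse → reconstruct → angles → windows → features → classify)
and persists each stage's artifact; `inst/cli/posturekit.R` wraps the same
functions as shell subcommands (`simulate`, `calibrate`, `fuse`,
`reconstruct`, `classify`, `run-all`).

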