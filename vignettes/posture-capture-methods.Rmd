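---
title: "Methods: IMU posture capture, joint angles and work-task recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IMU posture capture, joint angles and work-task recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posturekit)
```

posturekit estimates whole-body seated posture from body-worn 9-axis MARG
nodes (accelerometer + gyroscope + magnetometer), reconstructs joint flexion
angles over a 15-segment rigid body model, and recognizes which seated work
task the wearer is performing from windowed joint-angle features. This
vignette is the package's own account of the models, the tunable parameters,
the numerical choices, and what the built-in simulator does and does not
emulate.

## Frames and conventions

Three frames are used throughout. The *global* (navigation) frame has x
pointing north, y east and z toward the ground. The *sensor* frame is each
node's own axes; the *body* frame of a segment coincides with the global
frame while the wearer holds the north-facing neutral stance (arms down,
standing straight), which is how the fixed sensor-to-body mounting offset is
observed directly.

Rotations are unit quaternions, scalar-first `(q0, q1, q2, q3)`, Hamilton
convention. `q` and `-q` encode the same rotation, so constructors
canonicalize to `q0 >= 0`; tests compare rotations with the sign-insensitive
geodesic distance `quat_angle()`. Euler angles follow the ZYX
(yaw-pitch-roll) order; at gimbal lock (`|pitch| = 90` degrees) roll is set
to 0 and the heading is reported entirely in yaw, a documented tie-break
that makes the conversion deterministic.

The accelerometer is read in gravity-reaction convention: a level, static
sensor reports `(0, 0, +1)` g, i.e. the sensor-frame image of the global
down axis. This makes the static attitude formulas and the fusion
objective's gravity reference `(0, 0, 1)` mutually consistent with the
z-down global frame.

## Magnetometer calibration

Hard iron offsets the magnetometer locus; axis-aligned soft iron scales it.
Raw readings are modeled as lying on an axis-aligned ellipsoid

$$\left(\frac{H_x - e_x}{a}\right)^2 + \left(\frac{H_y - e_y}{b}\right)^2 +
  \left(\frac{H_z - e_z}{c}\right)^2 = 1,$$

fitted by linear least squares on the expanded quadric
`A x^2 + B y^2 + C z^2 + D x + E y + F z = 1` (no cross terms, so
direction-dependent coupling beyond per-axis scaling is deliberately out of
model). The center is the hard-iron offset; completing the square gives the
semi-axes `a, b, c`. The field modulus `R` is taken as the geometric mean
`(abc)^{1/3}`, so sphere data returns `a = b = c = R` and ellipsoid data
returns its true semi-axes unchanged. Calibration maps a raw reading
component-wise through `(raw - offset) * R / semiaxis`, which sends the
fitted ellipsoid onto a sphere of radius `R`.

The fit needs direction coverage: at least 9 samples, and a design matrix of
full rank. A wand-wave confined to a plane makes the quadric unidentifiable
and raises a `DegenerateCoverage`-class error rather than returning garbage.
Gyro bias is the mean angular rate over the initial still interval (minimum
1 s); the accelerometer bias estimate is the deviation of the mean measured
specific force from a unit-norm gravity reaction. White noise is left in
place — averaging it out is the fusion filter's job.

## Static attitude and gradient-descent fusion

With the sensor quasi-static (accelerometer norm within 20% of 1 g), roll
and pitch follow from the gravity direction and yaw from the
tilt-compensated horizontal field:

$$\phi = \operatorname{atan2}(a_y, a_z), \quad
  \theta = \arcsin(-a_x / g), \quad
  \psi = -\operatorname{atan2}(h_{Gy}, h_{Gx}),$$

with the `arcsin` argument clipped to `[-1, 1]` so accelerometer noise near
the poles cannot produce `NaN`. The tilt compensation uses the standard form
`h_{Gx} = h_x\cos\theta + h_y\sin\theta\sin\phi + h_z\sin\theta\cos\phi`;
this is the only form under which a level, north-facing sensor with a
dipping field reads zero yaw for any roll.

The runtime filter is a complementary gradient-descent (Madgwick-style)
update. Per frame, the quaternion derivative from the gyroscope,
`0.5 q (0, omega)`, is corrected by the normalized gradient of a stacked
alignment objective — gravity reference `(0,0,1)` and magnetic reference
`(b_x, 0, b_z)`, the measured field rotated to global by the current
estimate and flattened to the x-z plane (recomputed every step, the standard
magnetic-distortion guard) — scaled by the gain `beta`, then integrated at
the sample spacing and re-normalized. The gradient is analytic (`J^T f`) and
is property-tested against finite differences.

Two gains exist because two regimes exist:

* `xi` (default 0.1) is the step gain of the *static* initialisation
  iteration `q <- q - xi * grad/|grad|`. A fixed-length normalized step can
  only orbit the solution at radius `xi`, so the step is damped by the
  residual norm `min(1, |f|)`: full-length far away, contracting near the
  solution. Fifty damped iterations pull a 10-degree initial error below
  half a degree.
* `beta` (default 0.1) is the runtime filter gain: the weight of the field
  correction against gyro integration. `beta = 0` is pure integration (it
  inherits the full gyro bias drift, about 30 degrees per minute at 0.5
  deg/s bias); larger `beta` suppresses drift at the cost of admitting more
  accelerometer/magnetometer noise. Terminal static error is non-increasing
  in `beta` over the tested range 0 to 0.1 down to the noise floor.

Neither gain is dictated by the physics; 0.1 is a conventional default for
consumer MEMS noise levels and both are configurable everywhere they appear.

The mounting offset `qSB` (sensor to body segment) is assumed rigid. It is
read off during the neutral stance — where body equals global, so the fused
sensor-to-global track *is* the mounting — by sign-aligned averaging of at
least 1 s of frames, which measurably beats any single-frame estimate under
noise. Thereafter `qBG(t) = qSG(t) qSB^*`.

## Skeleton and joint angles

The body is a rigid tree of 15 segments rooted at the pelvis: pelvis, waist,
spine, chest, head, left/right shoulder, upper arm, forearm, thigh and calf.
Ten worn nodes instrument the chest, pelvis, arms and legs; the head and
shoulders inherit the chest node's quaternion, and the waist/spine inherit
their trunk neighbors — the node-to-segment map is a column of the model, so
a full 15-node placement works unchanged.

Neutral-pose directions are: trunk and head up, shoulders lateral, arms and
legs down. Segment lengths come from an anthropometric fraction table scaled
by stature (default 1.70 m) and can be overridden per segment; no segment
lengths are dictated by the method itself, only by the wearer.

Forward kinematics walks the tree from the pelvis: each endpoint is
`D1 = D0 + rotate(qBG, l * u)` and every child's start point is bound to its
parent's endpoint, so connectivity is conserved *by construction* (the tests
assert the gap is exactly zero) and segment length is conserved to floating
point at every frame. The pelvis root is held at the origin: the target
tasks are seated, and joint angles are translation-invariant anyway.

A joint flexion angle is the inverse cosine of the clamped normalized dot
product of the two adjacent segment vectors, in `[0, 180]` degrees —
symmetric, and invariant under any global heading rotation. Eight channels
are emitted: breast flexion BF (chest vs. waist), waist flexion WF (waist
vs. thigh, averaged over sides), shoulder SFl/SFr (upper arm vs. chest —
the adjacent-segment reading; vertical-referenced shoulder elevation would
be a different, non-adjacent convention and is not used), elbow EFl/EFr and
knee KFl/KFr. In the neutral stance the elbows, knees and breast read 0
(collinear segments) while arms-down shoulder flexion reads near 180 by
construction of the adjacent-segment rule.

## Windowing and the 23 features

Joint-angle series are cut into 1000 ms windows with 50% overlap (stride of
half a window, trailing partial window dropped), giving
`floor((N - w)/(w/2)) + 1` windows for `N` samples — 599 windows for 120 000
samples at 400 Hz. Per window and channel, 23 features are extracted:

* 12 time-domain: mean, median, standard deviation, median absolute
  deviation (unscaled, `median |x - med|`), 25th and 75th percentiles,
  interquartile range, skewness (`m3 / m2^{3/2}`), excess kurtosis
  (`m4 / m2^2 - 3`), variance, Shannon entropy of a 16-bin histogram
  (natural log), and spectral entropy of the normalized one-sided power
  spectrum (DC excluded).
* 6 frequency/autoregressive: dominant frequency, its power, its share of
  total power, plus the main peak value and the second peak's height and
  frequency of an order-4 Yule-Walker AR power spectrum evaluated on a
  257-point grid up to Nyquist.
* 5 band powers over equal-width bands spanning 0–10 Hz, the band where
  seated body motion lives.

Degenerate (constant) windows return 0 for skewness, kurtosis, both
entropies and all spectral quantities, so a feature vector never contains
`NaN`. Histogram bin count (16), AR order (4), band layout (5 × 2 Hz) and
the spectral conventions are free choices of this package — standard ones
for motion feature extraction — and are parameters of `extract_features()`.
The entire extractor is verified against a formula-level independent
reimplementation to 1e-9 on seeded noise.

## Classifier evaluation

A stratified 20% test split is carved out first and never touched during
model selection. The remainder is split into 10 stratified folds; per
classifier family the fold-model with the highest validation accuracy is
selected and evaluated once on the test split. Five classical families are
included: multinomial logistic regression, CART decision tree, RBF SVM
(cost 1), random forest (100 trees) and k-NN (k = 5) — hyperparameters are
configurable and deliberately default-valued rather than tuned. Features are
standardized by training-set statistics inside each fit.

Accuracy, precision, recall and F1 are support-weighted averages over
classes (F1 is the per-class harmonic mean before weighting). ROC AUC and
AUPRC are micro-averaged one-vs-rest: the one-hot truth matrix is flattened
against the class-probability matrix and treated as a single binary problem;
AUPRC uses step-interpolated average precision. The whole evaluation is
deterministic given its seed.

## The simulator, and what passing tests do not show

The simulator inverts the sensing model: from a scripted body-to-global
quaternion trajectory (single-axis waveforms per segment, blended out of the
neutral stance over a 1 s smoothstep) it derives the sensor-frame angular
rate from the quaternion log between frames, the accelerometer as the
sensor-frame gravity reaction, and the magnetometer as the sensor-frame
field (default `(0.25, 0, 0.4)` gauss, a mid-latitude field with downward
dip) pushed through the *inverse* of the calibration model. Corruption —
gyro bias and white noise, accelerometer noise, hard iron, axis scales,
magnetometer noise — is then added, with defaults at consumer-MEMS orders of
magnitude (0.04 deg/s gyro noise, 5 mg accelerometer noise, 2 mgauss
magnetometer noise). All randomness flows from one seed; identical seeds
give bit-identical traces.

The task-dataset generator emulates four seated work archetypes as
per-channel mean posture plus a sinusoid (reciting: upright with fast small
elbow oscillation; reading: forward lean, moderate elbow motion; browsing:
slight lean, low-amplitude motion; music: relaxed with large slow trunk
sway), with within-class Gaussian jitter of the mean (sd 2 degrees) and
amplitude (10%), random phase, and 0.5-degree measurement noise, in
5-second blocks so adjacent windows share a posture state. These classes are
separable *by construction*: the classification acceptance check is a
property of the pipeline (features preserve the separation; the evaluation
machinery is correct), not a reproduction of field performance on recorded
participants.

Known, deliberate simplifications: the accelerometer carries no linear
acceleration term (the tasks are quasi-static and the static-attitude
formula assumes it); no soft-tissue artifact; no magnetic disturbance
transients; soft iron is axis-aligned only, mirroring the calibration model
class. Real recordings violate all four to some degree, so passing the
synthetic round trips bounds algorithmic error, not field error.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 10 s scripted round trips
at 400 Hz for fusion accuracy; a 60 s static trace for drift suppression;
500–1500 wand-wave points for calibration; 8 s at 200 Hz for the knee
round trip; 100 windows per class (at the 50 Hz joint-angle analysis rate)
for classification — sizes chosen so the full suite runs in well under a
minute of filter time while every check operates in its asymptotic regime.

Other numerical tie-breaks worth knowing: gradient steps are skipped when
the gradient norm falls below 1e-12 (already converged); fold-model ties in
validation accuracy keep the first fold; quantiles use R's default type 7;
the Hermite resampler's default method estimates nodal derivatives with FMM
(not-a-knot-style) end conditions and therefore reproduces cubic
polynomials exactly, while the `"monotone"` option swaps in
shape-preserving PCHIP derivatives — no single cubic Hermite scheme is both
cubic-exact and overshoot-free, so both are offered and the default favors
exactness.
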