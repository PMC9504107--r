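#' Static attitude from gravity and the geomagnetic field
#'
#' Closed-form roll/pitch from the accelerometer followed by
#' tilt-compensated yaw from the magnetometer, valid for a quasi-static
#' sensor (accelerometer norm within 20% of 1 g):
#' `roll = atan2(ay, az)`, `pitch = asin(-ax / g)`, and yaw is
#' `-atan2(hGy, hGx)` with the field rotated to the horizontal plane.
#'
#' The global frame has x north, y east and z toward the ground, and the
#' accelerometer is read in gravity-reaction convention: a level sensor
#' reports `(0, 0, +1)` g.
#'
#' @param accel accelerometer 3-vector, g.
#' @param mag calibrated magnetometer 3-vector, gauss.
#' @return numeric 3-vector `c(roll, pitch, yaw)` in radians.
#' @export
initial_euler <- function(accel, mag) {
  g <- sqrt(sum(accel^2))
  if (abs(g - 1) > 0.2)
    pk_stop("posturekit_not_static",
            sprintf("accelerometer norm %.3f g outside the quasi-static gate [0.8, 1.2]", g))
  if (sqrt(sum(mag^2)) < 1e-12)
    pk_stop("posturekit_zero_vector", "magnetometer reading is zero")
  roll <- atan2(accel[2], accel[3])
  pitch <- asin(max(-1, min(1, -accel[1] / g)))
  hGx <- mag[1] * cos(pitch) + mag[2] * sin(pitch) * sin(roll) +
    mag[3] * sin(pitch) * cos(roll)
  hGy <- mag[2] * cos(roll) - mag[3] * sin(roll)
  yaw <- -atan2(hGy, hGx)
  c(roll, pitch, yaw)
}

#' Static attitude quaternion
#'
#' [quat_from_euler()] applied to [initial_euler()]: the initial
#' sensor-to-global quaternion captured while the wearer holds the
#' north-facing neutral pose. Because the body frame coincides with the
#' global frame in that pose, the same quaternion also serves as the
#' sensor-to-body mounting estimate.
#'
#' @inheritParams initial_euler
#' @return unit quaternion (sensor to global).
#' @export
initial_quaternion <- function(accel, mag) quat_from_euler(initial_euler(accel, mag))

#' Field-alignment error of an orientation estimate
#'
#' The vector part of `q* (0, nG) q - (0, nS)`: the reference direction `nG`
#' (global frame) rotated into the sensor frame by the current estimate,
#' minus the measured direction `nS`. Zero exactly when `q` maps `nS` onto
#' `nG`.
#'
#' @param q unit quaternion (sensor to global).
#' @param nG reference direction in the global frame (normalized internally).
#' @param nS measured direction in the sensor frame (normalized internally).
#' @return numeric 3-vector residual.
#' @export
objective_error <- function(q, nG, nS) {
  nGn <- sqrt(sum(nG^2)); nSn <- sqrt(sum(nS^2))
  if (nGn < 1e-12 || nSn < 1e-12)
    pk_stop("posturekit_zero_vector", "reference and measured directions must be non-zero")
  quat_rotate(quat_conjugate(q), nG / nGn) - nS / nSn
}

# Stacked gravity + magnetic-field gradient of the alignment objective
# (analytic J^T f for reference directions (0,0,1) and (bx,0,bz); the
# magnetic reference is re-derived each call from the current estimate by
# rotating the measurement to global and flattening it to the x-z plane).
marg_gradient <- function(q, accel, mag) {
  an <- sqrt(sum(accel^2)); mn <- sqrt(sum(mag^2))
  if (an < 1e-12 || mn < 1e-12)
    pk_stop("posturekit_zero_vector", "accelerometer and magnetometer must be non-zero")
  a <- accel / an; m <- mag / mn
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  h <- quat_rotate(q, m)
  bx <- sqrt(h[1]^2 + h[2]^2); bz <- h[3]

  fg1 <- 2 * (x * z - w * y) - a[1]
  fg2 <- 2 * (w * x + y * z) - a[2]
  fg3 <- 2 * (0.5 - x^2 - y^2) - a[3]
  fb1 <- 2 * bx * (0.5 - y^2 - z^2) + 2 * bz * (x * z - w * y) - m[1]
  fb2 <- 2 * bx * (x * y - w * z) + 2 * bz * (w * x + y * z) - m[2]
  fb3 <- 2 * bx * (w * y + x * z) + 2 * bz * (0.5 - x^2 - y^2) - m[3]

  c(-2 * y * fg1 + 2 * x * fg2 +
      (-2 * bz * y) * fb1 + (-2 * bx * z + 2 * bz * x) * fb2 + (2 * bx * y) * fb3,
    2 * z * fg1 + 2 * w * fg2 - 4 * x * fg3 +
      (2 * bz * z) * fb1 + (2 * bx * y + 2 * bz * w) * fb2 + (2 * bx * z - 4 * bz * x) * fb3,
    -2 * w * fg1 + 2 * z * fg2 - 4 * y * fg3 +
      (-4 * bx * y - 2 * bz * w) * fb1 + (2 * bx * x + 2 * bz * z) * fb2 +
      (2 * bx * w - 4 * bz * y) * fb3,
    2 * x * fg1 + 2 * y * fg2 +
      (-4 * bx * z + 2 * bz * x) * fb1 + (-2 * bx * w + 2 * bz * y) * fb2 +
      (2 * bx * x) * fb3)
}

#' One normalized gradient-descent step toward field alignment
#'
#' `q <- q - xi * grad(f) / |grad(f)|`, followed by re-normalization, where
#' `f` stacks the gravity objective (reference `(0, 0, 1)`) and the magnetic
#' objective (reference `(bx, 0, bz)` derived from the current estimate).
#' Iterating from a rough guess under static conditions converges to the
#' attitude implied by the two field measurements.
#'
#' A fixed-length normalized step can only orbit the solution at radius
#' `xi`, so the step is additionally damped by the residual norm `|f|`
#' (capped at 1): far from the solution the step has length `xi`, close to
#' it the iteration contracts. If the gradient norm is below `1e-12` the
#' estimate is already converged and returned unchanged.
#'
#' @param q current unit quaternion estimate (sensor to global).
#' @param accel accelerometer 3-vector, g.
#' @param mag calibrated magnetometer 3-vector, gauss.
#' @param xi step gain (default 0.1).
#' @return updated unit quaternion.
#' @export
gradient_step <- function(q, accel, mag, xi = 0.1) {
  grad <- marg_gradient(q, accel, mag)
  gn <- sqrt(sum(grad^2))
  if (gn < 1e-12) return(quat(q))
  damp <- min(1, residual_norm(q, accel, mag))
  quat(as.numeric(q) - xi * damp * grad / gn)
}

residual_norm <- function(q, accel, mag) {
  a <- accel / sqrt(sum(accel^2)); m <- mag / sqrt(sum(mag^2))
  h <- quat_rotate(q, m)
  b <- c(sqrt(h[1]^2 + h[2]^2), 0, h[3])
  sqrt(sum(objective_error(q, c(0, 0, 1), a)^2) +
         sum(objective_error(q, b, m)^2))
}

#' Fuse a MARG trace into a per-frame orientation track
#'
#' Complementary gradient-descent fusion: each frame the quaternion
#' derivative from the gyroscope, `0.5 * q (x) (0, omega)`, is corrected by
#' the normalized gradient of the gravity + magnetic alignment objective
#' scaled by the filter gain `beta`, then integrated at the sample spacing
#' and re-normalized. The gyroscope carries the short-term motion; the field
#' sensors bound the drift.
#'
#' @param trace a calibrated [imu_trace()] (gyro deg/s, accel g, mag gauss).
#' @param q0 initial unit quaternion, typically [initial_quaternion()] on the
#'   still interval. Default: computed from the first sample.
#' @param beta filter gain (default 0.1); `beta = 0` is pure gyro integration.
#' @return an [orientation_track()] with the per-frame `qSG`.
#' @export
fuse_trace <- function(trace, q0 = NULL, beta = 0.1) {
  t <- trace$t
  n <- length(t)
  if (n > 1L && any(diff(t) <= 0))
    pk_stop("posturekit_non_monotone_time", "timestamps must be strictly increasing")
  if (is.null(q0)) q0 <- initial_quaternion(trace$accel[1, ], trace$mag[1, ])
  d2r <- pi / 180
  Q <- matrix(0, n, 4)
  q <- as.numeric(quat(q0))
  Q[1, ] <- q
  for (i in seq_len(n - 1L) + 1L) {
    dt <- t[i] - t[i - 1L]
    wv <- trace$gyro[i, ] * d2r
    # qdot = 0.5 * q (x) (0, omega)
    qd <- 0.5 * c(
      -q[2] * wv[1] - q[3] * wv[2] - q[4] * wv[3],
      q[1] * wv[1] + q[3] * wv[3] - q[4] * wv[2],
      q[1] * wv[2] - q[2] * wv[3] + q[4] * wv[1],
      q[1] * wv[3] + q[2] * wv[2] - q[3] * wv[1]
    )
    if (beta > 0) {
      grad <- marg_gradient(q, trace$accel[i, ], trace$mag[i, ])
      gn <- sqrt(sum(grad^2))
      if (gn > 1e-12) qd <- qd - beta * grad / gn
    }
    q <- q + qd * dt
    q <- q / sqrt(sum(q * q))
    Q[i, ] <- q
  }
  # canonical sign per frame (q and -q are the same rotation)
  flip <- Q[, 1] < 0
  Q[flip, ] <- -Q[flip, , drop = FALSE]
  orientation_track(t, Q)
}

#' Estimate the fixed sensor-to-body mounting quaternion
#'
#' During the north-facing neutral stance the body frame coincides with the
#' global frame, so the sensor-to-global track over the still window directly
#' measures the sensor-to-body offset. Frames inside the window are averaged
#' ([quat_mean()]) to suppress noise. At least one second of frames is
#' required.
#'
#' @param track an [orientation_track()] covering the still pose.
#' @param still numeric length-2, start and end time (s) of the still window.
#' @return unit quaternion `qSB`.
#' @export
sensor_to_body <- function(track, still = c(track$t[1], track$t[1] + 2)) {
  idx <- which(track$t >= still[1] & track$t <= still[2])
  if (length(idx) < 2L || diff(range(track$t[idx])) < 1)
    pk_stop("posturekit_still_interval_too_short",
            "need at least 1 s of still frames to estimate the mounting offset")
  quat_mean(track$qSG[idx, , drop = FALSE])
}

#' Apply a mounting offset to an orientation track
#'
#' Derives the body-segment-to-global track `qBG(t) = qSG(t) (x) qSB*` from
#' the fused sensor track and the fixed sensor-to-body quaternion.
#'
#' @param track an [orientation_track()].
#' @param qSB unit mounting quaternion from [sensor_to_body()].
#' @return the track with `qSB` and `qBG` filled in.
#' @export
apply_mounting <- function(track, qSB) {
  qSBc <- quat_conjugate(quat(qSB))
  n <- nrow(track$qSG)
  qBG <- matrix(0, n, 4)
  for (i in seq_len(n)) qBG[i, ] <- quat_multiply(quat(track$qSG[i, ]), qSBc)
  track$qSB <- as.numeric(quat(qSB))
  track$qBG <- qBG
  track
}
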