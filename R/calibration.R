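#' Magnetometer calibration parameters
#'
#' Hard-iron offsets plus axis-aligned soft-iron scaling: raw readings are
#' modeled as lying on the axis-aligned ellipsoid
#' `((Hx-ex)/a)^2 + ((Hy-ey)/b)^2 + ((Hz-ez)/c)^2 = 1`, where `a,b,c` are the
#' ellipsoid semi-axes and `R` is the local geomagnetic field modulus taken as
#' the geometric mean of the semi-axes.
#'
#' @param offsets hard-iron offset 3-vector, gauss.
#' @param semiaxes ellipsoid semi-axes 3-vector, gauss, all positive.
#' @param R field modulus, gauss, positive.
#' @param rms residual RMS radial deviation of the fit set after calibration.
#' @return an object of class `"mag_calibration"`.
#' @export
mag_calibration <- function(offsets, semiaxes, R, rms = NA_real_) {
  offsets <- as.numeric(offsets); semiaxes <- as.numeric(semiaxes)
  if (length(offsets) != 3L || length(semiaxes) != 3L)
    pk_stop("posturekit_invalid_calibration", "offsets and semiaxes must be 3-vectors")
  if (any(semiaxes <= 0) || R <= 0)
    pk_stop("posturekit_invalid_calibration", "semiaxes and R must be positive")
  structure(list(offsets = offsets, semiaxes = semiaxes, R = R, rms = rms),
            class = "mag_calibration")
}

#' @export
print.mag_calibration <- function(x, ...) {
  cat("<mag_calibration>\n")
  cat(sprintf("  hard-iron offsets (gauss): %+.4f %+.4f %+.4f\n",
              x$offsets[1], x$offsets[2], x$offsets[3]))
  cat(sprintf("  semi-axes (gauss):          %.4f  %.4f  %.4f\n",
              x$semiaxes[1], x$semiaxes[2], x$semiaxes[3]))
  cat(sprintf("  field modulus R (gauss):    %.4f   fit RMS: %.2e\n", x$R, x$rms))
  invisible(x)
}

#' Fit an axis-aligned ellipsoid to raw magnetometer readings
#'
#' Linear least squares on the expanded quadric with no cross terms:
#' `A x^2 + B y^2 + C z^2 + D x + E y + F z = 1`. The center (hard-iron
#' offset) is `-D/2A, -E/2B, -F/2C` and the semi-axes follow from completing
#' the square. The field modulus `R` is reported as the geometric mean of the
#' semi-axes, so a sphere fit returns `a = b = c = R`.
#'
#' The wand-wave that produces the samples must cover enough directions for
#' the six quadric coefficients to be identifiable; near-planar coverage makes
#' the design matrix rank-deficient and is rejected.
#'
#' @param samples numeric `n x 3` matrix of raw readings, gauss, `n >= 9`.
#' @return a [mag_calibration()] with the residual RMS of the calibrated radii.
#' @export
fit_ellipsoid <- function(samples) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L)
    pk_stop("posturekit_invalid_calibration", "samples must be an n x 3 matrix")
  if (nrow(samples) < 9L)
    pk_stop("posturekit_degenerate_coverage",
            "need at least 9 samples spanning well-spread directions")
  M <- cbind(samples^2, samples)
  qr_M <- qr(M)
  if (qr_M$rank < 6L)
    pk_stop("posturekit_degenerate_coverage",
            "sample directions are too planar: quadric coefficients not identifiable")
  beta <- qr.coef(qr_M, rep(1, nrow(samples)))
  if (any(!is.finite(beta)) || any(beta[1:3] <= 0))
    pk_stop("posturekit_degenerate_coverage",
            "fit did not yield a real ellipsoid; improve direction coverage")
  center <- -beta[4:6] / (2 * beta[1:3])
  S <- 1 + sum(beta[1:3] * center^2)
  if (S <= 0)
    pk_stop("posturekit_degenerate_coverage", "degenerate quadric (non-positive radius)")
  semiaxes <- sqrt(S / beta[1:3])
  R <- prod(semiaxes)^(1 / 3)
  cal <- mag_calibration(center, semiaxes, R)
  calibrated <- apply_mag_calibration(cal, samples)
  radii <- sqrt(rowSums(calibrated^2))
  cal$rms <- sqrt(mean((radii - R)^2))
  cal
}

#' Apply a magnetometer calibration to raw readings
#'
#' Component-wise `(raw - offset) * R / semiaxis`: points on the fitted
#' ellipsoid map onto a sphere of radius `R` centered at the origin.
#'
#' @param cal a [mag_calibration()].
#' @param raw a 3-vector or `n x 3` matrix of raw readings, gauss.
#' @return calibrated readings with the shape of `raw`.
#' @export
apply_mag_calibration <- function(cal, raw) {
  scale <- cal$R / cal$semiaxes
  if (is.matrix(raw)) {
    sweep(sweep(raw, 2, cal$offsets, "-"), 2, scale, "*")
  } else {
    (as.numeric(raw) - cal$offsets) * scale
  }
}

#' Invert a magnetometer calibration (simulation helper)
#'
#' Maps a true field vector back to the distorted raw reading the sensor
#' would report under the given hard-iron offset and axis scaling.
#'
#' @param cal a [mag_calibration()].
#' @param field a 3-vector or `n x 3` matrix of true field vectors, gauss.
#' @return raw (distorted) readings.
#' @export
invert_mag_calibration <- function(cal, field) {
  scale <- cal$semiaxes / cal$R
  if (is.matrix(field)) {
    sweep(sweep(field, 2, scale, "*"), 2, cal$offsets, "+")
  } else {
    as.numeric(field) * scale + cal$offsets
  }
}

#' Inertial (gyroscope/accelerometer) error model
#'
#' The gyroscope is modeled as truth plus a constant per-axis bias plus white
#' noise; the accelerometer as the gravity reaction plus a constant bias plus
#' white noise.
#'
#' @param gyro_bias per-axis gyro bias, deg/s.
#' @param gyro_noise gyro white-noise standard deviation, deg/s.
#' @param accel_bias per-axis accelerometer bias, g.
#' @param gravity gravity magnitude seen by the accelerometer, g.
#' @return an object of class `"inertial_error_model"`.
#' @export
inertial_error_model <- function(gyro_bias = c(0, 0, 0), gyro_noise = 0,
                                 accel_bias = c(0, 0, 0), gravity = 1) {
  if (gyro_noise < 0)
    pk_stop("posturekit_invalid_calibration", "noise standard deviations must be >= 0")
  structure(list(gyro_bias = as.numeric(gyro_bias), gyro_noise = gyro_noise,
                 accel_bias = as.numeric(accel_bias), gravity = gravity),
            class = "inertial_error_model")
}

#' Estimate inertial sensor errors from a still interval
#'
#' Gyro bias is the mean angular rate over the still window (the neutral
#' standing pose held at the start of a recording); the accelerometer bias is
#' the deviation of the mean measured specific force from a unit-norm gravity
#' reaction along the same direction. At least one second of still samples is
#' required.
#'
#' @param trace an [imu_trace()].
#' @param still numeric length-2, start and end time (s) of the still window.
#' @return an [inertial_error_model()].
#' @export
estimate_inertial_errors <- function(trace, still = c(trace$t[1], trace$t[1] + 2)) {
  idx <- which(trace$t >= still[1] & trace$t <= still[2])
  if (length(idx) < 2L || diff(range(trace$t[idx])) < 1)
    pk_stop("posturekit_still_interval_too_short",
            "need at least 1 s of still samples to estimate sensor bias")
  gyro_bias <- colMeans(trace$gyro[idx, , drop = FALSE])
  gyro_noise <- mean(apply(trace$gyro[idx, , drop = FALSE], 2, stats::sd))
  a_mean <- colMeans(trace$accel[idx, , drop = FALSE])
  g <- sqrt(sum(a_mean^2))
  accel_bias <- a_mean - a_mean / g # magnitude error along the measured direction
  inertial_error_model(gyro_bias, gyro_noise, accel_bias, gravity = g)
}

#' Subtract estimated inertial biases from a trace
#'
#' Removes the constant gyro and accelerometer biases; white noise is left in
#' place for the fusion filter to average out.
#'
#' @param model an [inertial_error_model()].
#' @param trace an [imu_trace()].
#' @return the corrected [imu_trace()].
#' @export
correct_inertial <- function(model, trace) {
  trace$gyro <- sweep(trace$gyro, 2, model$gyro_bias, "-")
  trace$accel <- sweep(trace$accel, 2, model$accel_bias, "-")
  trace
}
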