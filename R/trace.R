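#' Construct a 9-axis IMU/MARG trace
#'
#' One sensor node's synchronized stream of accelerometer (g), gyroscope
#' (deg/s) and magnetometer (gauss) samples. Timestamps must be strictly
#' increasing; the nominal rate defaults to the reciprocal median sample
#' spacing.
#'
#' @param t numeric vector of timestamps in seconds.
#' @param accel,gyro,mag numeric `n x 3` matrices in g, deg/s and gauss.
#' @param node_id identifier of the worn node (e.g. segment name).
#' @param rate nominal sampling rate in Hz.
#' @return an object of class `"imu_trace"`.
#' @export
imu_trace <- function(t, accel, gyro, mag, node_id = "node", rate = NULL) {
  accel <- as_mat3(accel, "accel")
  gyro <- as_mat3(gyro, "gyro")
  mag <- as_mat3(mag, "mag")
  n <- length(t)
  if (n < 1L || nrow(accel) != n || nrow(gyro) != n || nrow(mag) != n)
    pk_stop("posturekit_malformed_trace", "t, accel, gyro and mag must have matching length")
  if (n > 1L && any(diff(t) <= 0))
    pk_stop("posturekit_non_monotone_time", "timestamps must be strictly increasing")
  if (is.null(rate)) rate <- if (n > 1L) 1 / stats::median(diff(t)) else NA_real_
  if (!is.na(rate) && rate <= 0)
    pk_stop("posturekit_malformed_trace", "sampling rate must be positive")
  structure(
    list(node_id = node_id, rate = rate, t = as.numeric(t),
         accel = accel, gyro = gyro, mag = mag),
    class = "imu_trace"
  )
}

as_mat3 <- function(x, what) {
  x <- as.matrix(x)
  if (ncol(x) != 3L || !is.numeric(x) || anyNA(x))
    pk_stop("posturekit_malformed_trace",
            sprintf("%s must be a numeric n x 3 matrix without NAs", what))
  dimnames(x) <- NULL
  x
}

#' @export
print.imu_trace <- function(x, ...) {
  cat(sprintf("<imu_trace> node '%s': %d samples @ %.1f Hz (%.2f s)\n",
              x$node_id, length(x$t), x$rate, diff(range(x$t))))
  invisible(x)
}

#' @export
length.imu_trace <- function(x) length(x$t)

#' Per-frame orientation track
#'
#' Holds the fused sensor-to-global quaternion `qSG` per frame and, once a
#' mounting offset has been applied, the fixed sensor-to-body quaternion
#' `qSB` and the derived body-segment-to-global track
#' `qBG(t) = qSG(t) (x) qSB*`.
#'
#' @param t timestamps in seconds.
#' @param qSG numeric `n x 4` matrix of unit quaternions, scalar first.
#' @param qSB optional fixed mounting quaternion.
#' @param qBG optional `n x 4` matrix of body-to-global quaternions.
#' @return an object of class `"orientation_track"`.
#' @export
orientation_track <- function(t, qSG, qSB = NULL, qBG = NULL) {
  qSG <- as.matrix(qSG)
  if (ncol(qSG) != 4L || nrow(qSG) != length(t))
    pk_stop("posturekit_malformed_trace", "qSG must be an n x 4 matrix matching t")
  structure(list(t = as.numeric(t), qSG = qSG, qSB = qSB, qBG = qBG),
            class = "orientation_track")
}

#' @export
print.orientation_track <- function(x, ...) {
  cat(sprintf("<orientation_track> %d frames (%.2f s)%s\n",
              length(x$t), diff(range(x$t)),
              if (is.null(x$qBG)) "" else ", mounting applied"))
  invisible(x)
}
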