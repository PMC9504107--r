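#' Scripted ground-truth motion for the simulator
#'
#' A motion script assigns each body segment a single-axis angular waveform:
#' the segment's body-to-global quaternion at time `t` is the rotation about
#' a fixed axis by `offset + amp * sin(2 pi freq t + phase)` (degrees).
#' Continuity is enforced by rejecting scripts whose inter-frame rotation
#' ever exceeds 10 degrees.
#'
#' @param duration script length, seconds.
#' @param rate frame rate, Hz.
#' @param segments named list; each element a list with `axis` (3-vector or
#'   one of `"x"`, `"y"`, `"z"`), `amp` (deg), `freq` (Hz), `offset` (deg),
#'   `phase` (rad), `start` (s; the segment holds the neutral pose until
#'   then and the waveform blends in over a 1 s smoothstep). Missing fields
#'   default to 0 (axis defaults to `"y"`).
#' @return a `"motion_script"`.
#' @export
motion_script <- function(duration, rate, segments) {
  if (duration <= 0 || rate <= 0)
    pk_stop("posturekit_malformed_trace", "duration and rate must be positive")
  axes <- list(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))
  segments <- lapply(segments, function(s) {
    ax <- s$axis %||% "y"
    if (is.character(ax)) ax <- axes[[ax]]
    ax <- ax / sqrt(sum(ax^2))
    out <- list(axis = ax, amp = s$amp %||% 0, freq = s$freq %||% 0,
                offset = s$offset %||% 0, phase = s$phase %||% 0,
                start = s$start %||% 0)
    # continuity: waveform slope and the 1 s ramp must stay below 10 deg/frame
    step <- (abs(out$amp) * 2 * pi * out$freq +
               (abs(out$offset) + abs(out$amp)) * 1.5) / rate
    if (step >= 10)
      pk_stop("posturekit_malformed_trace",
              "script is discontinuous: inter-frame rotation exceeds 10 degrees")
    out
  })
  structure(list(duration = duration, rate = rate, segments = segments),
            class = "motion_script")
}

script_times <- function(script) {
  seq(0, script$duration, by = 1 / script$rate)
}

#' Evaluate a motion script into quaternion trajectories
#'
#' @param script a [motion_script()].
#' @return named list of `n x 4` body-to-global quaternion matrices, plus a
#'   `t` attribute with the frame times.
#' @export
script_quaternions <- function(script) {
  t <- script_times(script)
  smoothstep <- function(u) {
    u <- pmin(1, pmax(0, u))
    u * u * (3 - 2 * u)
  }
  out <- lapply(script$segments, function(s) {
    env <- smoothstep(t - s$start) # 1 s blend out of the neutral pose
    ts <- pmax(0, t - s$start)
    ang <- env * (s$offset + s$amp * sin(2 * pi * s$freq * ts + s$phase)) * pi / 180
    Q <- cbind(cos(ang / 2), sin(ang / 2) %o% s$axis)
    flip <- Q[, 1] < 0
    Q[flip, ] <- -Q[flip, , drop = FALSE]
    Q
  })
  attr(out, "t") <- t
  out
}

#' Sensor corruption model for the simulator
#'
#' Defaults are of the order of a consumer-grade MEMS node: gyro white noise
#' of a few hundredths of a degree per second, milli-g accelerometer noise
#' and milli-gauss magnetometer noise, with zero bias and no hard-iron
#' distortion unless requested.
#'
#' @param gyro_bias per-axis gyro bias, deg/s.
#' @param gyro_noise gyro white-noise standard deviation, deg/s.
#' @param accel_noise accelerometer noise standard deviation, g.
#' @param mag_offset magnetometer hard-iron offset, gauss.
#' @param mag_scale per-axis soft-iron scale factors (1 = undistorted).
#' @param mag_noise magnetometer noise standard deviation, gauss.
#' @return a `"sensor_corruption"`.
#' @export
sensor_corruption <- function(gyro_bias = c(0, 0, 0), gyro_noise = 0.04,
                              accel_noise = 0.005, mag_offset = c(0, 0, 0),
                              mag_scale = c(1, 1, 1), mag_noise = 0.002) {
  if (gyro_noise < 0 || accel_noise < 0 || mag_noise < 0)
    pk_stop("posturekit_invalid_calibration", "noise standard deviations must be >= 0")
  structure(list(gyro_bias = as.numeric(gyro_bias), gyro_noise = gyro_noise,
                 accel_noise = accel_noise, mag_offset = as.numeric(mag_offset),
                 mag_scale = as.numeric(mag_scale), mag_noise = mag_noise),
            class = "sensor_corruption")
}

#' Synthesize a MARG trace from a known orientation trajectory
#'
#' The inverse sensor model: given the body-to-global quaternion trajectory
#' of one segment and the fixed sensor mounting, the gyroscope reads the
#' sensor-frame angular velocity (finite-differenced from the quaternion
#' log), the accelerometer reads the sensor-frame gravity reaction (linear
#' acceleration is omitted: the target tasks are seated and quasi-static)
#' and the magnetometer reads the sensor-frame geomagnetic field distorted
#' by the inverse hard-iron/scale model. Corruption noise and biases are
#' then added. The true sensor-to-global track is returned alongside.
#'
#' @param qbg `n x 4` matrix of body-to-global quaternions, or a
#'   [motion_script()] plus `segment` name.
#' @param t frame times, seconds (required when `qbg` is a matrix).
#' @param segment segment name when `qbg` is a script.
#' @param qSB fixed sensor-to-body mounting quaternion (default identity).
#' @param corruption a [sensor_corruption()].
#' @param field geomagnetic field in the global frame, gauss; default
#'   `c(0.25, 0, 0.4)`, a mid-latitude field with a downward dip.
#' @param seed integer seed for the corruption noise.
#' @param node_id node identifier for the emitted trace.
#' @return list with `trace` (an [imu_trace()]), `truth` (an
#'   [orientation_track()] of the true `qSG`) and `qbg` (the input truth).
#' @export
synthesize_trace <- function(qbg, t = NULL, segment = NULL,
                             qSB = quat_identity(),
                             corruption = sensor_corruption(),
                             field = c(0.25, 0, 0.4), seed = 1,
                             node_id = segment %||% "node") {
  if (inherits(qbg, "motion_script")) {
    qs <- script_quaternions(qbg)
    t <- attr(qs, "t")
    if (is.null(segment) || is.null(qs[[segment]]))
      pk_stop("posturekit_missing_segment_pose", "segment not present in the script")
    qbg <- qs[[segment]]
  }
  if (is.null(t) || nrow(qbg) != length(t))
    pk_stop("posturekit_malformed_trace", "qbg and t must have matching length")
  n <- nrow(qbg)
  qSB <- quat(qSB)
  # qBG = qSG (x) qSB*  =>  qSG = qBG (x) qSB
  qsg <- matrix(0, n, 4)
  for (i in seq_len(n)) qsg[i, ] <- quat_multiply(quat(qbg[i, ]), qSB)

  gyro <- matrix(0, n, 3)
  accel <- matrix(0, n, 3)
  magm <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    qi <- quat(qsg[i, ])
    if (i > 1L) {
      # rate over (t[i-1], t[i]] in the sensor frame, from the quaternion log
      dq <- quat_multiply(quat_conjugate(quat(qsg[i - 1L, ])), qi)
      v <- dq[2:4]
      vn <- sqrt(sum(v^2))
      ang <- 2 * atan2(vn, abs(dq[1]))
      dt <- t[i] - t[i - 1L]
      gyro[i, ] <- if (ang > 1e-12 && vn > 0) {
        sgn <- if (dq[1] >= 0) 1 else -1
        sgn * ang / dt * v / vn * 180 / pi
      } else c(0, 0, 0)
    }
    qic <- quat_conjugate(qi)
    accel[i, ] <- quat_rotate(qic, c(0, 0, 1))
    magm[i, ] <- quat_rotate(qic, field)
  }
  if (n > 1L) gyro[1, ] <- gyro[2, ]
  R <- sqrt(sum(field^2))
  mag_cal <- mag_calibration(corruption$mag_offset, corruption$mag_scale * R, R)
  magm <- invert_mag_calibration(mag_cal, magm)
  set.seed(seed)
  gyro <- sweep(gyro, 2, corruption$gyro_bias, "+") +
    matrix(stats::rnorm(3 * n, sd = corruption$gyro_noise), n)
  accel <- accel + matrix(stats::rnorm(3 * n, sd = corruption$accel_noise), n)
  magm <- magm + matrix(stats::rnorm(3 * n, sd = corruption$mag_noise), n)
  list(trace = imu_trace(t, accel, gyro, magm, node_id = node_id),
       truth = orientation_track(t, qsg, qSB = as.numeric(qSB), qBG = qbg),
       qbg = qbg)
}

#' Default per-task joint-angle recipes
#'
#' Four seated work-task archetypes expressed as per-channel mean posture
#' plus a sinusoidal waveform (degrees / Hz): reciting words (upright trunk,
#' small fast elbow oscillation), reading comprehension (forward lean,
#' moderate elbow motion), browsing (slight lean, low-amplitude arm motion)
#' and listening to music (relaxed posture, large slow trunk sway). Classes
#' are separable by construction at these effect sizes.
#'
#' @return named list of 4 recipes; each maps the 8 angle channels to
#'   `c(mean, amp, freq)` and carries the within-class jitter settings
#'   (`jitter_mean_sd` deg, `jitter_amp_frac`, `noise_sd` deg).
#' @export
task_recipes_default <- function() {
  rec <- function(BF, WF, SFl, SFr, EFl, EFr, KFl, KFr) {
    list(channels = list(BF = BF, WF = WF, SFl = SFl, SFr = SFr,
                         EFl = EFl, EFr = EFr, KFl = KFl, KFr = KFr),
         jitter_mean_sd = 2, jitter_amp_frac = 0.1, noise_sd = 0.5)
  }
  list(
    recite = rec(BF = c(20, 3, 1.0), WF = c(95, 2, 0.3),
                 SFl = c(160, 3, 0.8), SFr = c(158, 3, 0.8),
                 EFl = c(92, 8, 1.2), EFr = c(88, 8, 1.2),
                 KFl = c(90, 2, 0.2), KFr = c(90, 2, 0.2)),
    reading = rec(BF = c(32, 4, 0.6), WF = c(84, 3, 0.3),
                  SFl = c(150, 4, 0.5), SFr = c(147, 4, 0.5),
                  EFl = c(70, 5, 0.6), EFr = c(66, 5, 0.6),
                  KFl = c(92, 2, 0.2), KFr = c(92, 2, 0.2)),
    browse = rec(BF = c(10, 2, 0.3), WF = c(100, 2, 0.2),
                 SFl = c(168, 2, 0.3), SFr = c(164, 2, 0.4),
                 EFl = c(40, 3, 0.4), EFr = c(44, 3, 0.4),
                 KFl = c(96, 2, 0.2), KFr = c(96, 2, 0.2)),
    music = rec(BF = c(16, 12, 0.2), WF = c(106, 6, 0.15),
                SFl = c(174, 3, 0.2), SFr = c(174, 3, 0.2),
                EFl = c(14, 4, 0.15), EFr = c(16, 4, 0.15),
                KFl = c(100, 4, 0.15), KFr = c(100, 4, 0.15))
  )
}

#' Generate a labeled synthetic work-task joint-angle dataset
#'
#' Emits, per task, enough short joint-angle series to yield
#' `n_per_class` one-second windows at 50% overlap. Each series is a
#' five-second block whose recipe parameters receive Gaussian within-class
#' jitter (mean posture and waveform amplitude), on top of white measurement
#' noise, emulating between-window posture variability of a participant
#' repeating the same task. All randomness flows from the single seed.
#'
#' @param n_per_class windows per task (default 100).
#' @param recipes list of task recipes, see [task_recipes_default()].
#' @param rate joint-angle series rate, Hz (default 50: joint angles vary
#'   slowly and are analyzed far below the raw 400 Hz sensor rate).
#' @param window_ms,overlap the windowing the dataset is sized for.
#' @param seed integer seed.
#' @return list with `series` (per class, a list of `"joint_angles"`
#'   blocks) and `labels` (integer vector matching `series`).
#' @export
generate_task_dataset <- function(n_per_class = 100,
                                  recipes = task_recipes_default(),
                                  rate = 50, window_ms = 1000, overlap = 0.5,
                                  seed = 7) {
  set.seed(seed)
  block_s <- 5
  w <- round(rate * window_ms / 1000)
  wins_per_block <- floor((block_s * rate - w) / (w * (1 - overlap))) + 1
  n_blocks <- ceiling(n_per_class / wins_per_block)
  t <- seq(0, block_s - 1 / rate, by = 1 / rate)
  series <- vector("list", length(recipes))
  for (ci in seq_along(recipes)) {
    r <- recipes[[ci]]
    blocks <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      df <- data.frame(t = t)
      for (ch in names(r$channels)) {
        p <- r$channels[[ch]]
        mu <- p[1] + stats::rnorm(1, sd = r$jitter_mean_sd)
        amp <- p[2] * (1 + stats::rnorm(1, sd = r$jitter_amp_frac))
        phase <- stats::runif(1, 0, 2 * pi)
        y <- mu + amp * sin(2 * pi * p[3] * t + phase) +
          stats::rnorm(length(t), sd = r$noise_sd)
        df[[ch]] <- pmin(180, pmax(0, y))
      }
      blocks[[b]] <- joint_angles(df)
    }
    series[[ci]] <- blocks
  }
  names(series) <- names(recipes)
  list(series = series, labels = seq_along(recipes),
       windows_per_class = n_blocks * wins_per_block)
}

#' Piecewise-cubic Hermite resampling of a time series
#'
#' Resamples timestamped values onto a uniform grid at the target rate with
#' third-order (cubic) Hermite interpolation. The default `"cubic"` method
#' estimates nodal derivatives from a C2 cubic spline with not-a-knot-style
#' end conditions and reproduces cubic polynomials exactly; the
#' `"monotone"` method uses shape-preserving PCHIP derivatives, which never
#' overshoot monotone data at the cost of cubic exactness.
#'
#' @param t timestamps, strictly increasing, at least 4 points.
#' @param y values: a numeric vector or a matrix resampled per column.
#' @param target_rate output rate, Hz.
#' @param method `"cubic"` (default) or `"monotone"`.
#' @return list with `t` (the uniform output grid spanning the input
#'   support) and `y`.
#' @export
hermite_resample <- function(t, y, target_rate, method = c("cubic", "monotone")) {
  method <- match.arg(method)
  if (length(t) < 4L)
    pk_stop("posturekit_too_few_points", "Hermite resampling needs at least 4 points")
  if (any(diff(t) <= 0))
    pk_stop("posturekit_non_monotone_time", "timestamps must be strictly increasing")
  grid <- seq(t[1], t[length(t)], by = 1 / target_rate)
  interp_one <- function(col) {
    if (method == "cubic") {
      stats::splinefun(t, col, method = "fmm")(grid)
    } else {
      pracma::pchip(t, col, grid)
    }
  }
  out <- if (is.matrix(y)) {
    if (nrow(y) != length(t))
      pk_stop("posturekit_malformed_trace", "y must have one row per timestamp")
    apply(y, 2, interp_one)
  } else {
    if (length(y) != length(t))
      pk_stop("posturekit_malformed_trace", "t and y must have matching length")
    interp_one(as.numeric(y))
  }
  list(t = grid, y = out)
}
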