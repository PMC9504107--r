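static_fields <- function(q, field = c(0.25, 0, 0.4)) {
  qc <- quat_conjugate(q)
  list(accel = quat_rotate(qc, c(0, 0, 1)), mag = quat_rotate(qc, field))
}

test_that("static attitude closed forms reproduce constructed poses", {
  # level, north-facing
  expect_equal(initial_euler(c(0, 0, 1), c(0.3, 0, 0.5)), c(0, 0, 0))
  # pure 30 degree pitch
  e <- initial_euler(c(-0.5, 0, sqrt(1 - 0.25)), c(0.3, 0, 0.5))
  expect_equal(e[1], 0)
  expect_equal(e[2], 30 * pi / 180, tolerance = 1e-12)
  # field rotated 45 degrees about vertical at level attitude -> yaw = -45
  m <- quat_rotate(quat_from_euler(c(0, 0, pi / 4)), c(0.3, 0, 0.5))
  e <- initial_euler(c(0, 0, 1), m)
  expect_equal(e[3], -pi / 4, tolerance = 1e-12)
  # 45 degree heading case: a sensor yawed +45 reads the field rotated by -45
  f <- static_fields(quat_from_euler(c(0, 0, pi / 4)))
  expect_equal(initial_euler(f$accel, f$mag), c(0, 0, pi / 4), tolerance = 1e-12)
})

test_that("static attitude recovers arbitrary poses through the quaternion", {
  expect_equal(as.numeric(initial_quaternion(c(0, 0, 1), c(0.3, 0, 0.5))),
               c(1, 0, 0, 0))
  f <- static_fields(quat_from_euler(c(pi / 2, 0, 0)))
  expect_equal(as.numeric(initial_quaternion(f$accel, f$mag)),
               c(sqrt(2) / 2, sqrt(2) / 2, 0, 0), tolerance = 1e-12)
  set.seed(31)
  for (i in 1:20) {
    e <- c(runif(1, -2, 2), runif(1, -1.2, 1.2), runif(1, -3, 3))
    f <- static_fields(quat_from_euler(e))
    q <- initial_quaternion(f$accel, f$mag)
    expect_lt(quat_angle(q, quat_from_euler(e)), 1e-6)
    expect_equal(as.numeric(q),
                 as.numeric(quat_from_euler(initial_euler(f$accel, f$mag))))
  }
})

test_that("the quasi-static gate rejects dynamic samples", {
  expect_error(initial_euler(c(0, 0, 1.5), c(0.3, 0, 0.5)),
               class = "posturekit_not_static")
  expect_error(initial_euler(c(0, 0, 1), c(0, 0, 0)),
               class = "posturekit_zero_vector")
})

test_that("the alignment residual vanishes exactly at the solution", {
  expect_equal(objective_error(quat(c(1, 0, 0, 0)), c(0, 0, 1), c(0, 0, 1)),
               c(0, 0, 0))
  set.seed(32)
  for (i in 1:10) {
    q <- random_quat()
    nG <- rnorm(3)
    nS <- quat_rotate(quat_conjugate(q), nG / sqrt(sum(nG^2)))
    expect_equal(objective_error(q, nG, nS), c(0, 0, 0), tolerance = 1e-12)
  }
  # misaligned inputs: validated against a direct sandwich computation
  r <- objective_error(quat(c(1, 0, 0, 0)), c(0, 0, 1), c(1, 0, 0))
  expect_equal(r, c(0, 0, 1) - c(1, 0, 0))
  expect_error(objective_error(quat(c(1, 0, 0, 0)), c(0, 0, 0), c(1, 0, 0)),
               class = "posturekit_zero_vector")
})

test_that("the analytic gradient matches finite differences of |f|^2 / 2", {
  set.seed(33)
  a <- c(0.1, 0.2, 0.95); m <- c(0.3, -0.1, 0.4)
  q <- quat(c(0.9, 0.2, -0.3, 0.1))
  an <- a / sqrt(sum(a^2)); mn <- m / sqrt(sum(m^2))
  h <- quat_rotate(q, mn)
  b <- c(sqrt(h[1]^2 + h[2]^2), 0, h[3]) # reference frozen at q, as in the step
  fraw <- function(qv) {
    w <- qv[1]; x <- qv[2]; y <- qv[3]; z <- qv[4]
    fg <- c(2 * (x * z - w * y) - an[1], 2 * (w * x + y * z) - an[2],
            2 * (0.5 - x^2 - y^2) - an[3])
    fb <- c(2 * b[1] * (0.5 - y^2 - z^2) + 2 * b[3] * (x * z - w * y) - mn[1],
            2 * b[1] * (x * y - w * z) + 2 * b[3] * (w * x + y * z) - mn[2],
            2 * b[1] * (w * y + x * z) + 2 * b[3] * (0.5 - x^2 - y^2) - mn[3])
    0.5 * sum(fg^2) + 0.5 * sum(fb^2)
  }
  grad <- posturekit:::marg_gradient(q, a, m)
  eps <- 1e-6
  num <- vapply(1:4, function(i) {
    d <- numeric(4); d[i] <- eps
    (fraw(as.numeric(q) + d) - fraw(as.numeric(q) - d)) / (2 * eps)
  }, 1)
  expect_equal(grad, num, tolerance = 1e-5)
})

test_that("gradient descent converges from a perturbed static guess", {
  truth <- quat_from_euler(c(0.2, -0.1, 0.7))
  f <- static_fields(truth)
  # exact solution: the step is a no-op
  q_at <- gradient_step(truth, f$accel, f$mag)
  expect_lt(quat_angle(q_at, truth), 1e-6)
  # 10 degree perturbation, 50 iterations at xi = 0.1
  q <- quat_multiply(truth, quat_from_euler(c(10 * pi / 180, 0, 0)))
  for (i in 1:50) q <- gradient_step(q, f$accel, f$mag, xi = 0.1)
  expect_lt(quat_angle(q, truth), 0.5)
})

test_that("fusion holds a static fixed point and tracks a known rotation", {
  # all-zero gyro, static fields, q0 = truth -> constant track
  truth <- quat_from_euler(c(0.1, 0.2, -0.5))
  f <- static_fields(truth)
  t <- seq(0, 1, by = 1 / 400)
  n <- length(t)
  trace <- imu_trace(t, matrix(f$accel, n, 3, byrow = TRUE),
                     matrix(0, n, 3), matrix(f$mag, n, 3, byrow = TRUE))
  track <- fuse_trace(trace, q0 = truth, beta = 0.1)
  drift <- max(apply(track$qSG, 1, function(q) quat_angle(quat(q), truth, degrees = FALSE)))
  expect_lt(drift, 1e-6)

  # noiseless 90 deg/s yaw for 1 s -> final yaw 90 degrees
  ang <- 90 * t * pi / 180
  Q <- cbind(cos(ang / 2), 0, 0, sin(ang / 2))
  syn <- synthesize_trace(Q, t = t, corruption = sensor_corruption(
    gyro_noise = 0, accel_noise = 0, mag_noise = 0))
  track <- fuse_trace(syn$trace, q0 = quat(c(1, 0, 0, 0)), beta = 0.1)
  yaw <- quat_to_euler(quat(track$qSG[n, ]))[3] * 180 / pi
  expect_lt(abs(yaw - 90), 0.5)
})

test_that("field correction suppresses gyro-bias drift monotonically in beta", {
  t <- seq(0, 60, by = 1 / 100)
  n <- length(t)
  Q <- matrix(rep(c(1, 0, 0, 0), each = n), n)
  syn <- synthesize_trace(Q, t = t, seed = 34, corruption = sensor_corruption(
    gyro_bias = c(0, 0, 0.5), gyro_noise = 0.02, accel_noise = 0.002,
    mag_noise = 0.001))
  err <- vapply(c(0, 0.01, 0.05, 0.1), function(b) {
    track <- fuse_trace(syn$trace, q0 = quat(c(1, 0, 0, 0)), beta = b)
    quat_angle(quat(track$qSG[n, ]), quat(c(1, 0, 0, 0)))
  }, 1)
  expect_gt(err[1], 25) # pure integration drifts ~30 degrees
  expect_lt(err[4], 2)
  expect_true(all(diff(err) <= 0.01)) # non-increasing down to the noise floor
})

test_that("non-monotone timestamps are rejected by the filter", {
  t <- c(0, 0.01, 0.005)
  tr <- list(t = t, accel = cbind(0, 0, c(1, 1, 1)), gyro = matrix(0, 3, 3),
             mag = matrix(0.3, 3, 3), rate = 100)
  class(tr) <- "imu_trace"
  expect_error(fuse_trace(tr, q0 = quat(c(1, 0, 0, 0))),
               class = "posturekit_non_monotone_time")
})

test_that("mounting offset is recovered in the neutral pose and Eq-consistency holds", {
  # identity mount: body track equals sensor track
  truth <- quat(c(1, 0, 0, 0))
  f <- static_fields(truth)
  t <- seq(0, 2, by = 1 / 400)
  n <- length(t)
  trace <- imu_trace(t, matrix(f$accel, n, 3, byrow = TRUE), matrix(0, n, 3),
                     matrix(f$mag, n, 3, byrow = TRUE))
  track <- fuse_trace(trace, beta = 0.1)
  qsb <- sensor_to_body(track, still = c(0, 2))
  expect_lt(quat_angle(qsb, quat(c(1, 0, 0, 0))), 1e-6)

  # sensor mounted rotated 90 degrees about the limb axis: neutral qBG = identity
  mount <- quat_from_euler(c(0, 0, pi / 2))
  syn <- synthesize_trace(matrix(rep(c(1, 0, 0, 0), each = n), n), t = t,
                          qSB = mount, corruption = sensor_corruption(
                            gyro_noise = 0, accel_noise = 0, mag_noise = 0))
  track <- fuse_trace(syn$trace, beta = 0.1)
  qsb <- sensor_to_body(track, still = c(0, 2))
  expect_lt(quat_angle(qsb, mount), 0.1)
  mounted <- apply_mounting(track, qsb)
  expect_lt(max(apply(mounted$qBG, 1, function(q)
    quat_angle(quat(q), quat(c(1, 0, 0, 0))))), 0.1)
  # frame-wise consistency: qBG (x) qSB == qSG
  for (i in seq(1, n, by = 200)) {
    back <- quat_multiply(quat(mounted$qBG[i, ]), quat(mounted$qSB))
    expect_equal(as.numeric(back), as.numeric(quat(track$qSG[i, ])),
                 tolerance = 1e-9)
  }
})

test_that("averaging still frames beats a single-frame mounting estimate", {
  set.seed(35)
  t <- seq(0, 2, by = 1 / 400)
  n <- length(t)
  truth <- quat_from_euler(c(0.1, -0.2, 0.4))
  syn <- synthesize_trace(matrix(rep(c(1, 0, 0, 0), each = n), n), t = t,
                          qSB = truth, seed = 35,
                          corruption = sensor_corruption(gyro_noise = 0.2,
                                                         accel_noise = 0.02,
                                                         mag_noise = 0.01))
  track <- fuse_trace(syn$trace, beta = 0.5)
  single <- quat_angle(quat(track$qSG[5, ]), truth)
  averaged <- quat_angle(sensor_to_body(track, still = c(0, 2)), truth)
  expect_lt(averaged, single)
})

test_that("a too-short still window is refused for mounting estimation", {
  track <- orientation_track(seq(0, 0.5, by = 0.01),
                             matrix(rep(c(1, 0, 0, 0), each = 51), 51))
  expect_error(sensor_to_body(track), class = "posturekit_still_interval_too_short")
})

test_that("every emitted quaternion is unit-norm", {
  set.seed(36)
  t <- seq(0, 2, by = 1 / 200)
  ang <- 40 * sin(2 * pi * 0.8 * t) * pi / 180
  Q <- cbind(cos(ang / 2), sin(ang / 2), 0, 0)
  syn <- synthesize_trace(Q, t = t, seed = 36)
  track <- fuse_trace(syn$trace, beta = 0.1)
  expect_lt(max(abs(sqrt(rowSums(track$qSG^2)) - 1)), 1e-9)
})
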