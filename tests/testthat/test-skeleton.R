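identity_pose <- function(model) {
  q <- lapply(model$segment, function(s) matrix(c(1, 0, 0, 0), 1))
  names(q) <- model$segment
  q
}

test_that("the default body model is a valid 15-segment pelvis-rooted tree", {
  model <- default_body_model(1.70)
  expect_s3_class(model, "body_model")
  expect_equal(nrow(model), 15)
  expect_true(all(model$length > 0))
  expect_error(default_body_model(lengths = c(tail = 1)),
               class = "posturekit_invalid_body_model")
  broken <- as.data.frame(model)
  broken$parent[broken$segment == "pelvis"] <- "head" # cycle, no root
  expect_error(body_model(broken), class = "posturekit_invalid_body_model")
})

test_that("identity quaternions produce the neutral-stance skeleton", {
  model <- default_body_model(1.70)
  poses <- propagate_positions(model, identity_pose(model))
  p <- poses$poses
  # every endpoint is the cumulative neutral-pose offset from the pelvis
  expect_equal(drop(p$pelvis$D0), c(0, 0, 0))
  expect_equal(drop(p$pelvis$D1), c(0, 0, -model$length[model$segment == "pelvis"]))
  trunk <- c("pelvis", "waist", "spine", "chest", "head")
  top <- drop(p$head$D1)
  expect_equal(top, c(0, 0, -sum(model$length[match(trunk, model$segment)])))
  # arms hang straight down from the lateral shoulder tips
  lw <- drop(p$left_forearm$D1)
  expect_equal(lw[2], -model$length[model$segment == "left_shoulder"])
  arm <- sum(model$length[model$segment %in% c("left_upper_arm", "left_forearm")])
  expect_equal(lw[3] - drop(p$chest$D1)[3], arm, tolerance = 1e-9) # z down
})

test_that("segments lacking a node inherit the chest/pelvis quaternion", {
  model <- default_body_model()
  q <- identity_pose(model)
  q <- q[!(names(q) %in% c("head", "left_shoulder", "right_shoulder",
                           "spine", "waist"))]
  expect_silent(propagate_positions(model, q))
  q$chest <- NULL
  expect_error(propagate_positions(model, q),
               class = "posturekit_missing_segment_pose")
})

test_that("a 90 degree thigh rotation displaces the knee horizontally", {
  model <- default_body_model()
  q <- identity_pose(model)
  # rotate the right thigh about the mediolateral (y) axis by +90 degrees:
  # the thigh swings from straight down to straight forward (x north)
  q$right_thigh <- matrix(as.numeric(quat_from_euler(c(0, pi / 2, 0))), 1)
  poses <- propagate_positions(model, q)
  hip <- drop(poses$poses$right_thigh$D0)
  knee <- drop(poses$poses$right_thigh$D1)
  lt <- model$length[model$segment == "right_thigh"]
  expect_equal(knee - hip, c(lt, 0, 0), tolerance = 1e-9)
})

test_that("connectivity and segment length are conserved at every frame", {
  model <- default_body_model()
  set.seed(41)
  t <- seq(0, 1, by = 0.02)
  q <- lapply(model$segment, function(s) {
    ang <- runif(1, -0.5, 0.5) * sin(2 * pi * runif(1, 0.2, 1) * t)
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    cbind(cos(ang / 2), sin(ang / 2) %o% ax)
  })
  names(q) <- model$segment
  poses <- propagate_positions(model, q)
  for (seg in model$segment) {
    row <- model[model$segment == seg, ]
    lens <- sqrt(rowSums((poses$poses[[seg]]$D1 - poses$poses[[seg]]$D0)^2))
    expect_lt(max(abs(lens - row$length)), 1e-9)
    if (!is.na(row$parent)) {
      gap <- poses$poses[[seg]]$D0 - poses$poses[[row$parent]]$D1
      expect_equal(max(abs(gap)), 0)
    }
  }
})

test_that("skeleton height is invariant under a global yaw", {
  model <- default_body_model()
  q0 <- identity_pose(model)
  yawq <- quat_from_euler(c(0, 0, 1.2))
  q1 <- lapply(q0, function(m) matrix(as.numeric(yawq), 1))
  height <- function(poses) {
    zs <- unlist(lapply(poses$poses, function(p) c(p$D0[, 3], p$D1[, 3])))
    diff(range(zs))
  }
  expect_equal(height(propagate_positions(model, q0)),
               height(propagate_positions(model, q1)), tolerance = 1e-9)
})

test_that("the flexion angle matches closed forms and is symmetric", {
  expect_equal(joint_angle(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(joint_angle(c(1, 0, 0), c(2, 0, 0)), 0)
  expect_equal(joint_angle(c(1, 0, 0), c(-1, 0, 0)), 180)
  expect_error(joint_angle(c(0, 0, 0), c(1, 0, 0)), class = "posturekit_zero_vector")
  set.seed(42)
  for (i in 1:10) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(joint_angle(a, b), joint_angle(b, a), tolerance = 1e-12)
    expect_true(joint_angle(a, b) >= 0 && joint_angle(a, b) <= 180)
  }
})

test_that("neutral stance gives collinear elbows and knees", {
  model <- default_body_model()
  angles <- joint_angle_series(propagate_positions(model, identity_pose(model)))
  expect_equal(angles$EFl, 0, tolerance = 1e-6)
  expect_equal(angles$EFr, 0, tolerance = 1e-6)
  expect_equal(angles$KFl, 0, tolerance = 1e-6)
  expect_equal(angles$KFr, 0, tolerance = 1e-6)
  expect_equal(angles$BF, 0, tolerance = 1e-6)
})

test_that("a scripted sitting pose reads 90 degree knees on both sides", {
  model <- default_body_model()
  q <- identity_pose(model)
  hip90 <- matrix(as.numeric(quat_from_euler(c(0, pi / 2, 0))), 1)
  q$left_thigh <- hip90
  q$right_thigh <- hip90 # thighs forward, calves still vertical
  angles <- joint_angle_series(propagate_positions(model, q))
  expect_equal(angles$KFl, 90, tolerance = 1e-9)
  expect_equal(angles$KFr, 90, tolerance = 1e-9)
})

test_that("joint angles are invariant under a global heading rotation", {
  model <- default_body_model()
  set.seed(43)
  q <- lapply(model$segment, function(s) matrix(as.numeric(random_quat()), 1))
  names(q) <- model$segment
  a0 <- joint_angle_series(propagate_positions(model, q))
  yawq <- quat_from_euler(c(0, 0, 0.9))
  qy <- lapply(q, function(m) matrix(as.numeric(quat_multiply(yawq, quat(m[1, ]))), 1))
  a1 <- joint_angle_series(propagate_positions(model, qy))
  expect_equal(as.matrix(a0[-1]), as.matrix(a1[-1]), tolerance = 1e-9)
})

test_that("a scripted knee waveform survives the full sensing round trip", {
  # thigh fixed at +85 degrees (seated), calf swinging: knee angle
  # theta(t) = 45 - 30 sin(2 pi 0.5 (t - 2)) after the 2 s neutral hold
  rate <- 200
  script <- motion_script(8, rate, segments = list(
    right_thigh = list(axis = "y", offset = 85, amp = 0, freq = 0, start = 2),
    right_calf = list(axis = "y", offset = 40, amp = 30, freq = 0.5,
                      start = 2, phase = 0)
  ))
  qs <- script_quaternions(script)
  t <- attr(qs, "t")
  model <- default_body_model()
  tracks <- list()
  for (seg in names(qs)) {
    syn <- synthesize_trace(qs[[seg]], t = t, seed = 44,
                            corruption = sensor_corruption(gyro_noise = 0,
                                                           accel_noise = 0,
                                                           mag_noise = 0))
    track <- fuse_trace(syn$trace, beta = 0.1)
    tracks[[seg]] <- apply_mounting(track, sensor_to_body(track, c(0, 1.9)))$qBG
  }
  # uninstrumented segments held in the neutral pose
  for (seg in setdiff(model$segment, names(qs)))
    tracks[[seg]] <- matrix(c(1, 0, 0, 0), 1)
  angles <- joint_angle_series(propagate_positions(model, tracks), t = t)
  truth_q <- lapply(qs, identity)
  truth <- joint_angle_series(propagate_positions(
    model, c(truth_q, tracks[setdiff(model$segment, names(qs))])), t = t)
  late <- t > 3 # past convergence and ramp-in
  rms <- sqrt(mean((angles$KFr[late] - truth$KFr[late])^2))
  expect_lt(rms, 2)
  # and the truth itself matches the scripted waveform
  theta <- abs(85 - (40 + 30 * sin(2 * pi * 0.5 * pmax(0, t - 2))))
  expect_lt(max(abs(truth$KFr[late] - theta[late])), 1e-6)
})
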