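NODE_CSV_HEADER <- c("t", "ax_g", "ay_g", "az_g",
                     "gx_dps", "gy_dps", "gz_dps",
                     "mx_gauss", "my_gauss", "mz_gauss")

#' Read a sensor-node CSV into an IMU trace
#'
#' Expects the column layout `t, ax_g, ay_g, az_g, gx_dps, gy_dps, gz_dps,
#' mx_gauss, my_gauss, mz_gauss`; the unit suffixes (g, deg/s, gauss) are
#' part of the contract and are validated. Non-monotone timestamps are
#' rejected.
#'
#' @param path CSV file path.
#' @param node_id node identifier; defaults to the file name.
#' @return an [imu_trace()].
#' @export
read_node_csv <- function(path, node_id = NULL) {
  if (!file.exists(path))
    pk_stop("posturekit_malformed_csv", paste("no such file:", path))
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) pk_stop("posturekit_malformed_csv", conditionMessage(e)))
  if (length(names(df)) != length(NODE_CSV_HEADER))
    pk_stop("posturekit_malformed_csv",
            paste("expected 10 columns:", paste(NODE_CSV_HEADER, collapse = ",")))
  base_ok <- identical(sub("_[^_]*$", "", names(df)), sub("_[^_]*$", "", NODE_CSV_HEADER))
  if (!identical(names(df), NODE_CSV_HEADER)) {
    if (base_ok)
      pk_stop("posturekit_unit_mismatch",
              "channel unit suffixes differ from the g / dps / gauss contract")
    pk_stop("posturekit_malformed_csv",
            paste("expected header:", paste(NODE_CSV_HEADER, collapse = ",")))
  }
  if (!all(vapply(df, is.numeric, TRUE)) || anyNA(df))
    pk_stop("posturekit_malformed_csv", "all columns must be numeric without NAs")
  imu_trace(df$t, as.matrix(df[, 2:4]), as.matrix(df[, 5:7]), as.matrix(df[, 8:10]),
            node_id = node_id %||% sub("\\.csv$", "", basename(path)))
}

#' Write an IMU trace to a sensor-node CSV
#'
#' Values are written with enough digits that a write/read round trip is
#' lossless to 9 significant digits.
#'
#' @param trace an [imu_trace()].
#' @param path output CSV file path.
#' @return `path`, invisibly.
#' @export
write_node_csv <- function(trace, path) {
  m <- cbind(trace$t, trace$accel, trace$gyro, trace$mag)
  lines <- c(paste(NODE_CSV_HEADER, collapse = ","),
             apply(m, 1, function(r) paste(sprintf("%.10g", r), collapse = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Persist / load a magnetometer + gyro calibration as YAML
#'
#' Stores the seven ellipsoid numbers (three hard-iron offsets, three
#' semi-axes, field modulus) and the per-axis gyro bias.
#'
#' @param cal a [mag_calibration()].
#' @param gyro_bias per-axis gyro bias, deg/s.
#' @param path YAML file path.
#' @return `write_calibration_yaml`: `path` invisibly;
#'   `read_calibration_yaml`: list with `mag` (a [mag_calibration()]) and
#'   `gyro_bias`.
#' @export
write_calibration_yaml <- function(cal, gyro_bias = c(0, 0, 0), path) {
  yaml::write_yaml(list(
    mag = list(offsets = cal$offsets, semiaxes = cal$semiaxes, R = cal$R,
               rms = cal$rms),
    gyro_bias = as.numeric(gyro_bias)
  ), path)
  invisible(path)
}

#' @rdname write_calibration_yaml
#' @export
read_calibration_yaml <- function(path) {
  if (!file.exists(path))
    pk_stop("posturekit_calibration_missing", paste("no calibration file at", path))
  y <- yaml::read_yaml(path)
  list(mag = mag_calibration(y$mag$offsets, y$mag$semiaxes, y$mag$R,
                             y$mag$rms %||% NA_real_),
       gyro_bias = as.numeric(y$gyro_bias))
}

#' Write / read a body model as YAML
#'
#' @param model a [body_model()].
#' @param path YAML file path.
#' @export
write_body_model_yaml <- function(model, path) {
  yaml::write_yaml(list(segments = lapply(seq_len(nrow(model)), function(i) {
    r <- model[i, ]
    list(segment = r$segment, parent = if (is.na(r$parent)) NULL else r$parent,
         length = r$length, direction = c(r$ux, r$uy, r$uz),
         inherit = if (is.na(r$inherit)) NULL else r$inherit)
  })), path)
  invisible(path)
}

#' @rdname write_body_model_yaml
#' @export
read_body_model_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  body_model(do.call(rbind, lapply(y$segments, function(s) {
    data.frame(segment = s$segment, parent = s$parent %||% NA_character_,
               length = s$length, ux = s$direction[1], uy = s$direction[2],
               uz = s$direction[3], inherit = s$inherit %||% NA_character_,
               stringsAsFactors = FALSE)
  })))
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run with its default: filter
#' gains, windowing, classifier settings, simulation sizes and the seed.
#' Defaults are echoed to the log when the pipeline runs so a run is fully
#' reproducible from its log alone.
#'
#' @param out_dir output directory for stage artifacts.
#' @param seed master seed for every stochastic stage.
#' @param rate raw sensor rate, Hz.
#' @param beta fusion filter gain.
#' @param xi static-initialisation step gain.
#' @param window_ms,overlap feature windowing.
#' @param n_per_class synthetic windows per task.
#' @param stature participant height, meters, for the default body model.
#' @param classifier_config hyperparameter overrides, see
#'   [evaluate_classifiers()].
#' @return a validated `"run_config"` list.
#' @export
run_config <- function(out_dir = tempfile("posturekit_run_"), seed = 7,
                       rate = 400, beta = 0.1, xi = 0.1,
                       window_ms = 1000, overlap = 0.5, n_per_class = 100,
                       stature = 1.70, classifier_config = list()) {
  if (rate <= 0 || beta < 0 || xi <= 0 || window_ms <= 0 ||
      overlap < 0 || overlap >= 1 || n_per_class < 1)
    pk_stop("posturekit_invalid_config", "invalid pipeline configuration")
  structure(list(out_dir = out_dir, seed = as.integer(seed), rate = rate,
                 beta = beta, xi = xi, window_ms = window_ms, overlap = overlap,
                 n_per_class = n_per_class, stature = stature,
                 classifier_config = classifier_config),
            class = "run_config")
}

pk_log <- function(..., verbose = TRUE) {
  if (verbose) message(sprintf(...))
}

#' Run the full capture-to-classification pipeline on simulated data
#'
#' Chains every stage in pipeline order on built-in simulations:
#' magnetometer ellipsoid calibration and gyro-bias estimation on a
#' synthesized wand-wave and still interval, static attitude
#' initialisation, gradient-descent fusion of per-node MARG traces from a
#' scripted seated motion, skeleton reconstruction and joint-angle
#' extraction, then task-dataset generation, windowing, feature extraction
#' and five-classifier evaluation. Each stage's artifact is persisted under
#' `config$out_dir`; the whole run is deterministic given `config$seed` and
#' never mutates its inputs.
#'
#' @param config a [run_config()].
#' @param verbose log stage progress and paper-gap defaults to stderr.
#' @return list with the artifact paths, the joint-angle series, the
#'   feature dataset and the [evaluate_classifiers()] report.
#' @export
run_pipeline <- function(config = run_config(), verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pk_log("pipeline defaults: beta=%.3f xi=%.3f window=%d ms overlap=%.2f AR order=4 bands=5x2 Hz seed=%d",
         config$beta, config$xi, config$window_ms, config$overlap, config$seed,
         verbose = verbose)

  # -- calibrate: ellipsoid fit on a simulated wand wave with hard iron
  set.seed(config$seed)
  dirs <- matrix(stats::rnorm(500 * 3), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  field_R <- sqrt(sum(c(0.25, 0, 0.4)^2))
  true_cal <- mag_calibration(c(0.12, -0.05, 0.2), c(1.1, 1.0, 0.9) * field_R, field_R)
  cal <- fit_ellipsoid(invert_mag_calibration(true_cal, dirs * field_R))
  cal_path <- file.path(config$out_dir, "calibration.yaml")
  pk_log("calibrate: hard iron (%.3f, %.3f, %.3f) gauss, fit RMS %.2e",
         cal$offsets[1], cal$offsets[2], cal$offsets[3], cal$rms, verbose = verbose)

  # -- simulate the worn nodes: 2 s neutral stance then seated task motion
  script <- motion_script(
    duration = 6, rate = config$rate,
    segments = list(
      chest = list(axis = "y", offset = 10, amp = 6, freq = 0.4, start = 2),
      pelvis = list(axis = "y", offset = 0, amp = 0, freq = 0, start = 2),
      left_upper_arm = list(axis = "y", offset = 30, amp = 5, freq = 0.7, start = 2),
      right_upper_arm = list(axis = "y", offset = 32, amp = 5, freq = 0.7, start = 2),
      left_forearm = list(axis = "y", offset = -45, amp = 8, freq = 1.0, start = 2),
      right_forearm = list(axis = "y", offset = -48, amp = 8, freq = 1.0, start = 2),
      left_thigh = list(axis = "y", offset = -85, amp = 2, freq = 0.3, start = 2),
      right_thigh = list(axis = "y", offset = -85, amp = 2, freq = 0.3, start = 2),
      left_calf = list(axis = "y", offset = 5, amp = 2, freq = 0.3, start = 2),
      right_calf = list(axis = "y", offset = 5, amp = 2, freq = 0.3, start = 2)
    ))
  qs <- script_quaternions(script)
  tt <- attr(qs, "t")

  corruption <- sensor_corruption(gyro_bias = c(0.3, -0.2, 0.25),
                                  mag_offset = true_cal$offsets,
                                  mag_scale = true_cal$semiaxes / true_cal$R)
  tracks <- list()
  for (seg in names(qs)) {
    syn <- synthesize_trace(qs[[seg]], t = tt, qSB = quat_identity(),
                            corruption = corruption,
                            seed = config$seed + match(seg, names(qs)),
                            node_id = seg)
    trace <- syn$trace
    write_node_csv(trace, file.path(config$out_dir, paste0(seg, ".csv")))
    # correct: calibrated magnetometer + still-interval bias removal
    trace$mag <- apply_mag_calibration(cal, trace$mag)
    err <- estimate_inertial_errors(trace, still = c(0, 1.5))
    trace <- correct_inertial(err, trace)
    if (seg == "pelvis")
      write_calibration_yaml(cal, err$gyro_bias, cal_path)
    # initial state + fuse + mounting
    q0 <- initial_quaternion(colMeans(trace$accel[trace$t <= 1.5, ]),
                             colMeans(trace$mag[trace$t <= 1.5, ]))
    track <- fuse_trace(trace, q0 = q0, beta = config$beta)
    qsb <- sensor_to_body(track, still = c(0, 1.5))
    tracks[[seg]] <- apply_mounting(track, qsb)
  }
  pk_log("fuse: %d nodes x %d frames fused at beta=%.2f",
         length(tracks), length(tt), config$beta, verbose = verbose)

  # -- reconstruct + joint angles (script holds the neutral pose first)
  model <- default_body_model(config$stature)
  poses <- propagate_positions(model, lapply(tracks, function(x) x$qBG))
  angles <- joint_angle_series(poses, t = tt)
  angles_path <- file.path(config$out_dir, "angles.csv")
  utils::write.csv(angles, angles_path, row.names = FALSE)
  pk_log("reconstruct: %d frames, channels %s", nrow(angles),
         paste(angle_channels(angles), collapse = " "), verbose = verbose)

  # -- task dataset -> windows -> features -> classify
  task <- generate_task_dataset(n_per_class = config$n_per_class,
                                seed = config$seed)
  dataset <- build_dataset(task$series, task$labels,
                           window_ms = config$window_ms, overlap = config$overlap)
  features_path <- file.path(config$out_dir, "features.csv")
  write_feature_csv(dataset, features_path)
  report <- evaluate_classifiers(dataset, seed = config$seed,
                                 config = config$classifier_config)
  report_path <- file.path(config$out_dir, "report.json")
  write_report_json(report, report_path)
  pk_log("classify: %d windows, best test accuracy %.3f", nrow(dataset),
         max(vapply(report$classifiers, function(r) r$accuracy, 1)),
         verbose = verbose)

  list(calibration = cal_path, angles = angles_path, features = features_path,
       report = report_path, angle_series = angles, dataset = dataset,
       evaluation = report)
}

write_feature_csv <- function(dataset, path) {
  num <- vapply(dataset[-1], function(col) sprintf("%.10g", col),
                character(nrow(dataset)))
  lines <- c(paste(c("label", names(dataset)[-1]), collapse = ","),
             paste(as.character(dataset$label),
                   apply(num, 1, paste, collapse = ","), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

write_report_json <- function(report, path) {
  out <- lapply(report$classifiers, function(r)
    r[c("accuracy", "precision", "recall", "f1", "auc", "auprc", "fold_accuracy")])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
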