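#' Default 15-segment rigid body model
#'
#' The body is modeled as a rigid tree of 15 limb segments rooted at the
#' pelvis: pelvis, waist, spine, chest, head, left/right shoulder,
#' left/right upper arm, left/right forearm, left/right thigh and
#' left/right calf. Each segment stores its parent, length, neutral-pose
#' direction (unit vector in the global frame of the north-facing neutral
#' stance: trunk and head up, shoulders lateral, arms and legs down, with z
#' pointing toward the ground), the worn node supplying its quaternion, and
#' the segment whose quaternion it inherits when it carries no node of its
#' own (head and shoulders follow the chest node; waist and spine follow
#' their trunk neighbors).
#'
#' Segment lengths are an anthropometric table scaled linearly by stature;
#' any length can be overridden.
#'
#' @param stature participant height in meters (default 1.70).
#' @param lengths optional named numeric vector of per-segment length
#'   overrides, meters.
#' @return a `"body_model"`: data frame with columns `segment`, `parent`,
#'   `length`, `ux`, `uy`, `uz`, `inherit`.
#' @export
default_body_model <- function(stature = 1.70, lengths = NULL) {
  up <- c(0, 0, -1); down <- c(0, 0, 1)
  seg <- function(segment, parent, frac, u, inherit = NA_character_) {
    data.frame(segment = segment, parent = parent, length = frac * stature,
               ux = u[1], uy = u[2], uz = u[3], inherit = inherit,
               stringsAsFactors = FALSE)
  }
  m <- rbind(
    seg("pelvis", NA_character_, 0.050, up),
    seg("waist", "pelvis", 0.090, up, "pelvis"),
    seg("spine", "waist", 0.110, up, "chest"),
    seg("chest", "spine", 0.120, up),
    seg("head", "chest", 0.170, up, "chest"),
    seg("left_shoulder", "chest", 0.110, c(0, -1, 0), "chest"),
    seg("right_shoulder", "chest", 0.110, c(0, 1, 0), "chest"),
    seg("left_upper_arm", "left_shoulder", 0.186, down),
    seg("right_upper_arm", "right_shoulder", 0.186, down),
    seg("left_forearm", "left_upper_arm", 0.146, down),
    seg("right_forearm", "right_upper_arm", 0.146, down),
    seg("left_thigh", "pelvis", 0.245, down),
    seg("right_thigh", "pelvis", 0.245, down),
    seg("left_calf", "left_thigh", 0.246, down),
    seg("right_calf", "right_thigh", 0.246, down)
  )
  if (!is.null(lengths)) {
    bad <- setdiff(names(lengths), m$segment)
    if (length(bad))
      pk_stop("posturekit_invalid_body_model",
              paste("unknown segment(s):", paste(bad, collapse = ", ")))
    m$length[match(names(lengths), m$segment)] <- as.numeric(lengths)
  }
  body_model(m)
}

#' Validate a body model
#'
#' Checks the 15-segment tree structure: exactly the canonical segment set,
#' a single pelvis root, positive lengths, unit neutral directions and a
#' cycle-free connected path from the pelvis to every segment.
#'
#' @param m data frame with columns `segment`, `parent`, `length`,
#'   `ux`, `uy`, `uz` and optionally `inherit`.
#' @return the validated `"body_model"`.
#' @export
body_model <- function(m) {
  needed <- c("segment", "parent", "length", "ux", "uy", "uz")
  if (!all(needed %in% names(m)))
    pk_stop("posturekit_invalid_body_model",
            paste("body model needs columns:", paste(needed, collapse = ", ")))
  if (is.null(m$inherit)) m$inherit <- NA_character_
  canon <- c("pelvis", "waist", "spine", "chest", "head",
             "left_shoulder", "right_shoulder",
             "left_upper_arm", "right_upper_arm",
             "left_forearm", "right_forearm",
             "left_thigh", "right_thigh", "left_calf", "right_calf")
  if (!setequal(m$segment, canon) || anyDuplicated(m$segment))
    pk_stop("posturekit_invalid_body_model",
            "model must contain exactly the 15 canonical segments")
  roots <- m$segment[is.na(m$parent)]
  if (!identical(roots, "pelvis"))
    pk_stop("posturekit_invalid_body_model", "the pelvis must be the single root")
  if (any(m$length <= 0))
    pk_stop("posturekit_invalid_body_model", "segment lengths must be positive")
  u <- as.matrix(m[, c("ux", "uy", "uz")])
  if (any(abs(sqrt(rowSums(u^2)) - 1) > 1e-6))
    pk_stop("posturekit_invalid_body_model", "neutral directions must be unit vectors")
  # reachability from the root (also rejects cycles among non-root segments)
  reached <- "pelvis"
  repeat {
    nxt <- m$segment[!is.na(m$parent) & m$parent %in% reached & !(m$segment %in% reached)]
    if (!length(nxt)) break
    reached <- c(reached, nxt)
  }
  if (length(reached) != nrow(m))
    pk_stop("posturekit_invalid_body_model",
            "every segment must be connected to the pelvis without cycles")
  rownames(m) <- NULL
  class(m) <- c("body_model", "data.frame")
  m
}

# Topological order: parents before children.
model_order <- function(model) {
  ord <- "pelvis"
  repeat {
    nxt <- model$segment[!is.na(model$parent) & model$parent %in% ord &
                           !(model$segment %in% ord)]
    if (!length(nxt)) break
    ord <- c(ord, nxt)
  }
  ord
}

#' Propagate segment endpoint positions from the pelvis
#'
#' Forward kinematics over the rigid tree: for every segment, the endpoint is
#' `D1 = D0 + rotate(qBG, length * u)` where `u` is the segment's neutral
#' direction, and each child's start point is bound to its parent's endpoint,
#' walking depth-first from the pelvis root (held at `root_pos`). Segments
#' without a quaternion track of their own use the track named in their
#' `inherit` column; a segment with neither raises an error.
#'
#' @param model a [body_model()].
#' @param qbg named list of `n x 4` quaternion matrices (body-segment to
#'   global, scalar first), one entry per instrumented segment; a single
#'   quaternion is recycled over frames.
#' @param root_pos pelvis start position, meters (default origin).
#' @return a `"segment_poses"` list: per segment `D0`, `D1` (`n x 3`) and
#'   `qBG` (`n x 4`), plus the frame count.
#' @export
propagate_positions <- function(model, qbg, root_pos = c(0, 0, 0)) {
  qbg <- lapply(qbg, function(q) {
    q <- if (is.matrix(q)) q else matrix(as.numeric(q), 1)
    if (ncol(q) != 4L)
      pk_stop("posturekit_invalid_quaternion", "each qBG entry must be n x 4")
    q
  })
  n <- max(vapply(qbg, nrow, 1L))
  qbg <- lapply(qbg, function(q) if (nrow(q) == n) q else {
    if (nrow(q) != 1L)
      pk_stop("posturekit_missing_segment_pose", "quaternion tracks differ in length")
    q[rep(1L, n), , drop = FALSE]
  })
  resolve <- function(segment) {
    if (!is.null(qbg[[segment]])) return(qbg[[segment]])
    inh <- model$inherit[model$segment == segment]
    if (!is.na(inh) && !is.null(qbg[[inh]])) return(qbg[[inh]])
    pk_stop("posturekit_missing_segment_pose",
            sprintf("no quaternion track for segment '%s' (and no inherited node)", segment))
  }
  poses <- list()
  for (segment in model_order(model)) {
    row <- model[model$segment == segment, ]
    Q <- resolve(segment)
    D0 <- if (is.na(row$parent)) {
      matrix(rep(root_pos, each = n), n)
    } else {
      poses[[row$parent]]$D1
    }
    u <- c(row$ux, row$uy, row$uz) * row$length
    D1 <- D0
    for (i in seq_len(n)) D1[i, ] <- D0[i, ] + quat_rotate(Q[i, ], u)
    poses[[segment]] <- list(D0 = D0, D1 = D1, qBG = Q)
  }
  structure(list(poses = poses, n = n, model = model), class = "segment_poses")
}

#' Flexion angle between two limb-segment vectors
#'
#' The inverse cosine of the normalized dot product of the two segment
#' vectors, in degrees, clamped into `[0, 180]`. Symmetric in its arguments.
#'
#' @param parent_vec,child_vec numeric 3-vectors (`D1 - D0` of each segment).
#' @return angle in degrees.
#' @export
joint_angle <- function(parent_vec, child_vec) {
  np <- sqrt(sum(parent_vec^2)); nc <- sqrt(sum(child_vec^2))
  if (np < 1e-12 || nc < 1e-12)
    pk_stop("posturekit_zero_vector", "segment vectors must be non-zero")
  acos(max(-1, min(1, sum(parent_vec * child_vec) / (np * nc)))) * 180 / pi
}

#' Joint flexion-angle time series of the whole body
#'
#' Per frame, the flexion angles between adjacent limb-segment vectors:
#' breast flexion `BF` (chest vs. waist), waist flexion `WF` (waist vs.
#' thighs, averaged over sides), shoulder flexion `SFl`/`SFr` (upper arm vs.
#' chest), elbow flexion `EFl`/`EFr` (forearm vs. upper arm) and knee flexion
#' `KFl`/`KFr` (calf vs. thigh). All angles are relative geometry, so the
#' series is invariant under any global heading rotation of the skeleton.
#'
#' @param poses a `"segment_poses"` set from [propagate_positions()].
#' @param t optional timestamps (seconds); defaults to the frame index.
#' @return a `"joint_angles"` data frame with columns `t`, `BF`, `WF`,
#'   `SFl`, `SFr`, `EFl`, `EFr`, `KFl`, `KFr` (degrees).
#' @export
joint_angle_series <- function(poses, t = NULL) {
  p <- poses$poses
  n <- poses$n
  if (is.null(t)) t <- seq_len(n) - 1
  vec <- function(segment) p[[segment]]$D1 - p[[segment]]$D0
  v <- lapply(c(chest = "chest", waist = "waist",
                lua = "left_upper_arm", rua = "right_upper_arm",
                lfa = "left_forearm", rfa = "right_forearm",
                lth = "left_thigh", rth = "right_thigh",
                lcf = "left_calf", rcf = "right_calf"), vec)
  ang <- function(a, b) {
    out <- numeric(n)
    for (i in seq_len(n)) out[i] <- joint_angle(a[i, ], b[i, ])
    out
  }
  out <- data.frame(
    t = as.numeric(t),
    BF = ang(v$chest, v$waist),
    WF = (ang(v$waist, v$lth) + ang(v$waist, v$rth)) / 2,
    SFl = ang(v$chest, v$lua),
    SFr = ang(v$chest, v$rua),
    EFl = ang(v$lua, v$lfa),
    EFr = ang(v$rua, v$rfa),
    KFl = ang(v$lth, v$lcf),
    KFr = ang(v$rth, v$rcf)
  )
  joint_angles(out)
}

#' Joint-angle series container
#'
#' Validates a data frame of joint flexion angles: a `t` column plus angle
#' channels in degrees, all within `[0, 180]`.
#'
#' @param df data frame with column `t` and one column per angle channel.
#' @return the data frame with class `"joint_angles"`.
#' @export
joint_angles <- function(df) {
  if (!"t" %in% names(df))
    pk_stop("posturekit_malformed_trace", "joint-angle series needs a 't' column")
  chans <- setdiff(names(df), "t")
  if (!length(chans))
    pk_stop("posturekit_malformed_trace", "joint-angle series needs at least one channel")
  vals <- as.matrix(df[, chans, drop = FALSE])
  if (any(!is.finite(vals)) || any(vals < -1e-9) || any(vals > 180 + 1e-9))
    pk_stop("posturekit_malformed_trace", "joint angles must be finite and within [0, 180] degrees")
  class(df) <- c("joint_angles", "data.frame")
  df
}

angle_channels <- function(x) setdiff(names(x), "t")
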