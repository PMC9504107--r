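#' Unit quaternion construction
#'
#' Quaternions are stored scalar-first, `c(q0, q1, q2, q3)`, in the Hamilton
#' convention (right-handed, `ijk = -1`). Every constructor normalizes to unit
#' norm and canonicalizes the sign so that `q0 >= 0` (and, on the `q0 = 0`
#' boundary, the first non-zero component is positive): `q` and `-q` encode the
#' same rotation, and a fixed representative keeps comparisons deterministic.
#'
#' @param q numeric vector of length 4, scalar part first.
#' @param normalize normalize to unit norm (default `TRUE`).
#' @return numeric vector of length 4 with class `"quaternion"`.
#' @examples
#' quat(c(1, 0, 0, 0))
#' quat(c(-1, 0, 0, 0)) # canonicalized to (1, 0, 0, 0)
#' @export
quat <- function(q, normalize = TRUE) {
  if (!is.numeric(q) || length(q) != 4L || anyNA(q))
    pk_stop("posturekit_invalid_quaternion", "a quaternion needs 4 finite components")
  q <- as.numeric(q)
  if (normalize) {
    n <- sqrt(sum(q * q))
    if (n < 1e-12)
      pk_stop("posturekit_invalid_quaternion", "cannot normalize a zero quaternion")
    q <- q / n
  }
  # canonical sign: q0 >= 0; on the boundary, first non-zero component > 0
  nz <- which(abs(q) > 0)[1]
  if (q[nz] < 0) q <- -q
  structure(q, class = "quaternion")
}

#' @export
print.quaternion <- function(x, ...) {
  cat(sprintf("<quaternion> %.6f %+.6fi %+.6fj %+.6fk\n", x[1], x[2], x[3], x[4]))
  invisible(x)
}

quat_identity <- function() quat(c(1, 0, 0, 0), normalize = FALSE)

#' Hamilton product of two unit quaternions
#'
#' Composes rotations: `quat_multiply(a, b)` is the rotation `b` followed by
#' `a` (the usual `a %*% b` matrix order). The result is re-normalized.
#'
#' @param a,b unit quaternions (scalar-first numeric length-4).
#' @return unit quaternion.
#' @export
quat_multiply <- function(a, b) {
  quat(c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  ))
}

#' Quaternion conjugate (rotation inverse for unit quaternions)
#'
#' @param q unit quaternion.
#' @return unit quaternion with the vector part negated.
#' @export
quat_conjugate <- function(q) quat(c(q[1], -q[2], -q[3], -q[4]), normalize = FALSE)

#' Rotate a 3-vector by a unit quaternion
#'
#' Sandwich product `q (0, v) q*`; an isometry, so the norm of `v` is
#' preserved.
#'
#' @param q unit quaternion.
#' @param v numeric 3-vector.
#' @return rotated 3-vector.
#' @export
quat_rotate <- function(q, v) {
  # v' = v + 2 qv x (qv x v + q0 v), cheaper than the full sandwich
  qv <- q[2:4]
  t2 <- cross3(qv, v) + q[1] * v
  v + 2 * cross3(qv, t2)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Euler angles (ZYX / yaw-pitch-roll) to quaternion
#'
#' Intrinsic rotation sequence yaw about z, then pitch about y, then roll
#' about x; equivalently the matrix product `Rz(yaw) Ry(pitch) Rx(roll)`.
#'
#' @param euler numeric 3-vector `c(roll, pitch, yaw)` in radians.
#' @return unit quaternion.
#' @export
quat_from_euler <- function(euler) {
  cr <- cos(euler[1] / 2); sr <- sin(euler[1] / 2)
  cp <- cos(euler[2] / 2); sp <- sin(euler[2] / 2)
  cy <- cos(euler[3] / 2); sy <- sin(euler[3] / 2)
  quat(c(
    cr * cp * cy + sr * sp * sy,
    sr * cp * cy - cr * sp * sy,
    cr * sp * cy + sr * cp * sy,
    cr * cp * sy - sr * sp * cy
  ))
}

#' Quaternion to Euler angles (ZYX)
#'
#' Inverse of [quat_from_euler()]. Pitch is confined to `[-pi/2, pi/2]`. At
#' gimbal lock (`|pitch| = pi/2`) only the sum/difference of roll and yaw is
#' observable; the convention here is to set roll to 0 and report all the
#' heading in yaw.
#'
#' @param q unit quaternion.
#' @return numeric 3-vector `c(roll, pitch, yaw)` in radians.
#' @export
quat_to_euler <- function(q) {
  sp <- 2 * (q[1] * q[3] - q[4] * q[2])
  if (abs(sp) >= 1 - 1e-12) {
    pitch <- sign(sp) * pi / 2
    # roll fixed to 0; remaining rotation is pure yaw
    yaw <- 2 * atan2(q[4], q[1])
    return(c(0, pitch, yaw))
  }
  roll <- atan2(2 * (q[1] * q[2] + q[3] * q[4]), 1 - 2 * (q[2]^2 + q[3]^2))
  pitch <- asin(sp)
  yaw <- atan2(2 * (q[1] * q[4] + q[2] * q[3]), 1 - 2 * (q[3]^2 + q[4]^2))
  c(roll, pitch, yaw)
}

#' Angle between two rotations
#'
#' The geodesic distance on SO(3) between the rotations encoded by `a` and
#' `b`, insensitive to quaternion sign.
#'
#' @param a,b unit quaternions.
#' @param degrees return degrees (default) or radians.
#' @return non-negative rotation angle.
#' @export
quat_angle <- function(a, b = quat_identity(), degrees = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (sum(a * b) < 0) b <- -b
  # atan2 form stays accurate for near-identical rotations where acos loses
  # half the significant digits
  ang <- 4 * atan2(sqrt(sum((a - b)^2)), sqrt(sum((a + b)^2)))
  if (degrees) ang * 180 / pi else ang
}

#' Mean of a set of nearby unit quaternions
#'
#' Sign-aligns every row to the first quaternion, averages component-wise and
#' re-normalizes. Adequate for tightly clustered orientations such as frames
#' of a static pose; not a general rotation average.
#'
#' @param Q numeric matrix, one quaternion per row (scalar first).
#' @return unit quaternion.
#' @export
quat_mean <- function(Q) {
  Q <- as.matrix(Q)
  if (ncol(Q) != 4L) pk_stop("posturekit_invalid_quaternion", "need an n x 4 matrix")
  s <- drop(Q %*% Q[1, ])
  Q[s < 0, ] <- -Q[s < 0, , drop = FALSE]
  quat(colMeans(Q))
}
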