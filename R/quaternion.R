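# Quaternion utilities for body->world rotation and sagittal pitch extraction.
# Quaternions are stored (w, x, y, z), scalar first, one per row when vectorised.

.quat_as_matrix <- function(quat) {
  if (is.null(dim(quat))) {
    if (length(quat) != 4L)
      stop("quaternion must have 4 components (w, x, y, z)", call. = FALSE)
    quat <- matrix(quat, nrow = 1L)
  }
  if (ncol(quat) != 4L)
    stop("quaternion matrix must have 4 columns (w, x, y, z)", call. = FALSE)
  if (!all(is.finite(quat)))
    stop("non-finite quaternion component", call. = FALSE)
  quat
}

.check_unit_quat <- function(quat, tol = 1e-6) {
  nrm <- sqrt(rowSums(quat^2))
  if (any(abs(nrm - 1) > tol))
    stop("quaternion norm deviates from 1 beyond tolerance ", tol, call. = FALSE)
  quat / nrm
}

#' Rotate body-frame vectors into the world frame
#'
#' Applies the rotation encoded by unit quaternions (body -> world) to
#' body-frame vectors, e.g. accelerometer readings. Vectorised: `quat` may be
#' an `n x 4` matrix and `v` an `n x 3` matrix of per-sample readings.
#'
#' @param quat unit quaternion `(w, x, y, z)`, or an `n x 4` matrix of them.
#' @param v 3-vector in the body frame (m/s^2 for accelerations), or an
#'   `n x 3` matrix.
#' @return rotated vector(s) in the world frame, same shape as `v`.
#' @examples
#' rotate_to_world(c(1, 0, 0, 0), c(0, 0, 9.81))
#' @export
rotate_to_world <- function(quat, v) {
  quat <- .quat_as_matrix(quat)
  drop_out <- is.null(dim(v))
  if (drop_out) v <- matrix(v, nrow = 1L)
  if (ncol(v) != 3L) stop("vector must have 3 components", call. = FALSE)
  if (!all(is.finite(v))) stop("non-finite vector component", call. = FALSE)
  if (nrow(quat) == 1L && nrow(v) > 1L)
    quat <- quat[rep(1L, nrow(v)), , drop = FALSE]
  if (nrow(quat) != nrow(v))
    stop("quaternion and vector row counts differ", call. = FALSE)
  quat <- .check_unit_quat(quat)
  w <- quat[, 1L]; q <- quat[, 2:4, drop = FALSE]
  # v' = v + 2 w (q x v) + 2 q x (q x v)
  t1 <- .cross3(q, v)
  out <- v + 2 * w * t1 + 2 * .cross3(q, t1)
  if (drop_out) drop(out) else out
}

.cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

#' Foot pitch angle from orientation quaternion
#'
#' Extracts the sagittal-plane pitch (rotation about the mediolateral y axis)
#' using the aerospace ZYX Euler sequence, `asin(2(w*y - z*x))`. Positive
#' pitch means toe up (dorsiflexion of the foot segment). The asin argument
#' is clamped to `[-1, 1]` so gimbal-degenerate orientations near +/-90
#' degrees return the boundary value rather than NaN.
#'
#' @param quat unit quaternion `(w, x, y, z)` or `n x 4` matrix.
#' @return pitch angle(s) in degrees, in `[-90, 90]`.
#' @examples
#' compute_pitch(c(cos(pi / 12), 0, sin(pi / 12), 0)) # 30 degrees
#' @export
compute_pitch <- function(quat) {
  quat <- .check_unit_quat(.quat_as_matrix(quat))
  s <- 2 * (quat[, 1L] * quat[, 3L] - quat[, 4L] * quat[, 2L])
  s <- pmin(1, pmax(-1, s))
  asin(s) * 180 / pi
}

#' Quaternion for a pure pitch rotation
#'
#' Builds the unit quaternion for a rotation of `pitch_deg` degrees about the
#' mediolateral (y) axis, the inverse of [compute_pitch()] for pure sagittal
#' rotations. Used by the synthetic generator to emit orientation streams.
#'
#' @param pitch_deg pitch angle(s), degrees, positive = toe up.
#' @return `n x 4` quaternion matrix `(w, x, y, z)`.
#' @export
quat_from_pitch <- function(pitch_deg) {
  half <- pitch_deg * pi / 360
  cbind(cos(half), 0, sin(half), 0)
}
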