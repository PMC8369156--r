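#' @useDynLib adaptahrs, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Quaternion convention used throughout the package
# -------------------------------------------------
# Quaternions are plain numeric vectors of length 4 in scalar-first order
# (w, x, y, z), Hamilton product. A quaternion q denotes the attitude of a
# sensor (or marker cluster) with respect to the earth frame:
#
#   v_earth = q (x) (0, v_sensor) (x) q*
#
# equivalently v_earth = quat_to_rotmat(q) %*% v_sensor. This is the
# convention under which the published gradient-descent MARG filter
# equations hold verbatim, so an independent transliteration of that filter
# can be used as a cross-check. Orientation series are n x 4 matrices with
# one quaternion per row.

.quat_tol_unit <- 1e-6

assert_finite <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite numeric", name), call. = FALSE)
  }
  invisible(x)
}

#' Hamilton product of two quaternions
#'
#' Scalar-first (w, x, y, z) convention. The product `a %q% b` composes
#' rotations so that the rotation of `b` is applied first:
#' `quat_to_rotmat(quat_multiply(a, b)) == quat_to_rotmat(a) %*% quat_to_rotmat(b)`.
#'
#' @param a,b numeric(4) quaternions.
#' @return numeric(4) quaternion.
#' @export
quat_multiply <- function(a, b) {
  assert_finite(a, "a"); assert_finite(b, "b")
  stopifnot(length(a) == 4L, length(b) == 4L)
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

#' Quaternion conjugate
#' @param q numeric(4) quaternion.
#' @return numeric(4) quaternion; the inverse rotation for unit `q`.
#' @export
quat_conjugate <- function(q) {
  assert_finite(q, "q")
  c(q[1], -q[2], -q[3], -q[4])
}

#' Normalize a quaternion to unit norm
#' @param q numeric(4) quaternion.
#' @return unit quaternion.
#' @export
quat_normalize <- function(q) {
  assert_finite(q, "q")
  n <- sqrt(sum(q^2))
  if (n < 1e-300) stop("cannot normalize zero quaternion", call. = FALSE)
  q / n
}

#' Convert a unit quaternion to a rotation matrix
#'
#' Returns `R` such that `R %*% v` rotates `v` consistently with the
#' sandwich product `q (x) (0, v) (x) q*`.
#'
#' @param q unit quaternion (tolerance 1e-6 on the norm).
#' @return 3 x 3 rotation matrix.
#' @export
quat_to_rotmat <- function(q) {
  assert_finite(q, "q")
  if (abs(sqrt(sum(q^2)) - 1) > .quat_tol_unit) {
    stop("quaternion must be unit within 1e-6", call. = FALSE)
  }
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Shepperd's method: the reconstruction branch follows the largest of
#' trace-based candidates for numerical stability. The returned quaternion
#' has non-negative scalar part; q and -q denote the same rotation.
#'
#' @param R 3 x 3 rotation matrix.
#' @return unit quaternion (w, x, y, z).
#' @export
rotmat_to_quat <- function(R) {
  check_rotation_matrix(R)
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s, (R[1, 2] + R[2, 1]) / s,
           (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, 0.25 * s,
           (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  q <- quat_normalize(unname(q))
  if (q[1] < 0) q <- -q
  q
}

#' Validate a rotation matrix
#'
#' Checks orthonormality (`R %*% t(R) = I`) and `det(R) = +1`.
#'
#' @param R candidate 3 x 3 matrix.
#' @param tol tolerance on both checks.
#' @return `R`, invisibly; errors if the checks fail.
#' @export
check_rotation_matrix <- function(R, tol = 1e-6) {
  if (!is.matrix(R) || !all(dim(R) == c(3, 3)) || anyNA(R) || any(!is.finite(R))) {
    stop("R must be a finite 3 x 3 matrix", call. = FALSE)
  }
  if (max(abs(R %*% t(R) - diag(3))) > tol || abs(det(R) - 1) > tol) {
    stop("R is not orthonormal with det +1", call. = FALSE)
  }
  invisible(R)
}

#' One first-order gyroscope integration step
#'
#' Advances the attitude by the quaternion-rate increment
#' `dq = 0.5 * q (x) (0, omega)` over a step of `dt` seconds and
#' renormalizes: `q_new = normalize(q + dq * dt)`. This is the
#' gyroscope-only limit (correction gain beta = 0) of the complementary
#' filter update.
#'
#' @param q unit quaternion, current attitude.
#' @param omega numeric(3) angular rate in the sensor frame, rad/s.
#' @param dt step length in seconds, > 0.
#' @return unit quaternion.
#' @export
integrate_gyro <- function(q, omega, dt) {
  assert_finite(q, "q"); assert_finite(omega, "omega")
  stopifnot(length(omega) == 3L)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a positive number", call. = FALSE)
  }
  dq <- 0.5 * quat_multiply(q, c(0, omega))
  quat_normalize(q + dq * dt)
}

#' Helical (screw) rotation angle of a rotation matrix
#'
#' The single rotation angle about the helical axis carrying the identity
#' into `R`: `theta = acos((trace(R) - 1) / 2)` in degrees, in `[0, 180]`.
#' The acos argument is clamped to `[-1, 1]` to absorb floating-point
#' excursions of the trace.
#'
#' @param R 3 x 3 rotation matrix.
#' @return angle in degrees.
#' @export
helical_angle <- function(R) {
  check_rotation_matrix(R)
  arg <- (R[1, 1] + R[2, 2] + R[3, 3] - 1) / 2
  arg <- min(1, max(-1, arg))
  acos(arg) * 180 / pi
}

#' Helical (screw) rotation axis of a rotation matrix
#'
#' Unit rotation axis of `R`. For angles away from 180 degrees the axis is
#' read from the antisymmetric part of `R`; near 180 degrees (where that
#' part vanishes) it is recovered from the dominant diagonal of
#' `(R + I) / 2`, with the sign fixed so that the first nonzero component
#' is positive (at 180 degrees both signs describe the same rotation).
#'
#' @param R 3 x 3 rotation matrix with helical angle in (0, 180].
#' @return unit numeric(3) axis; `R %*% axis == axis`.
#' @export
helical_axis <- function(R) {
  check_rotation_matrix(R)
  theta <- helical_angle(R)
  if (theta < 1e-7) {
    stop("rotation angle is zero: helical axis undefined", call. = FALSE)
  }
  if (theta < 179.5) {
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    v / sqrt(sum(v^2))
  } else {
    # near 180 deg the antisymmetric part vanishes; use the exact algebra
    # (R + R^T)/2 = cos(t) I + (1 - cos(t)) u u^T, well conditioned there
    ct <- (R[1, 1] + R[2, 2] + R[3, 3] - 1) / 2
    S <- ((R + t(R)) / 2 - ct * diag(3)) / (1 - ct)
    j <- which.max(diag(S))
    u <- S[, j] / sqrt(max(S[j, j], .Machine$double.eps))
    u <- u / sqrt(sum(u^2))
    # for theta slightly below 180 the antisymmetric part still fixes the
    # sign; at exactly 180 make the first nonzero component positive
    v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
    if (sqrt(sum(v^2)) > 1e-9) {
      if (sum(u * v) < 0) u <- -u
    } else {
      nz <- which(abs(u) > 1e-12)[1]
      if (length(nz) && u[nz] < 0) u <- -u
    }
    unname(u)
  }
}

# Row-wise quaternion helpers on n x 4 matrices (vectorized hot paths).
quat_rows_multiply <- function(A, B) {
  cbind(
    A[, 1] * B[, 1] - A[, 2] * B[, 2] - A[, 3] * B[, 3] - A[, 4] * B[, 4],
    A[, 1] * B[, 2] + A[, 2] * B[, 1] + A[, 3] * B[, 4] - A[, 4] * B[, 3],
    A[, 1] * B[, 3] - A[, 2] * B[, 4] + A[, 3] * B[, 1] + A[, 4] * B[, 2],
    A[, 1] * B[, 4] + A[, 2] * B[, 3] - A[, 3] * B[, 2] + A[, 4] * B[, 1]
  )
}

quat_rows_conjugate <- function(A) {
  cbind(A[, 1], -A[, 2], -A[, 3], -A[, 4])
}

quat_rows_normalize <- function(A) {
  A / sqrt(rowSums(A^2))
}

# Rotate row vectors V (n x 3) by row quaternions Q (n x 4): sensor -> earth.
quat_rows_rotate <- function(Q, V) {
  P <- quat_rows_multiply(quat_rows_multiply(Q, cbind(0, V)), quat_rows_conjugate(Q))
  P[, 2:4, drop = FALSE]
}
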