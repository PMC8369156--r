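# Trunk-inclination kinematics: the one-dimensional signed helical angle
# between a distal (trunk) and a proximal (wheelchair) segment, referenced
# to a neutral pose.

#' Relative rotation of a distal segment in a proximal frame
#'
#' `R_rel = t(prox) %*% dist`, the distal attitude expressed in the
#' proximal frame. Pre-multiplying both inputs by a common world rotation
#' leaves the result unchanged.
#'
#' @param prox,dist 3 x 3 rotation matrices (segment attitudes).
#' @return 3 x 3 rotation matrix.
#' @export
relative_rotation <- function(prox, dist) {
  check_rotation_matrix(prox)
  check_rotation_matrix(dist)
  t(prox) %*% dist
}

as_quat_matrix <- function(x) {
  if (inherits(x, "orientation_series")) {
    list(time_s = x$time_s, q = orientation_quats(x))
  } else if (inherits(x, "frame_series")) {
    n <- length(x$time_s)
    Q <- matrix(NA_real_, n, 4)
    for (i in seq_len(n)) {
      if (isTRUE(x$valid[i])) Q[i, ] <- rotmat_to_quat(x$R[, , i])
    }
    list(time_s = x$time_s, q = Q)
  } else {
    stop("expected an orientation_series or frame_series", call. = FALSE)
  }
}

#' Signed helical trunk inclination relative to neutral pose
#'
#' Per sample, the relative rotation `R_rel(t)` of the trunk in the
#' wheelchair frame is referenced to the neutral sample,
#' `D(t) = t(R_rel(neutral)) %*% R_rel(t)`, and reduced to its helical
#' angle. The intrinsically non-negative helical angle is signed by
#' projecting the helical axis onto the wheelchair left-right (+y) axis
#' expressed in the referencing frame, so trunk flexion (forward pitch) is
#' positive and extension negative. The neutral sample is 0 degrees
#' exactly.
#'
#' Both inputs may be `orientation_series` (IMU route) or `frame_series`
#' (marker route); they must be time-aligned and equally long.
#'
#' @param trunk,chair distal and proximal orientation streams.
#' @param neutral_index index of the neutral-pose reference sample;
#'   defaults to the first sample valid in both streams.
#' @return an `inclination_series` (`NA` where either stream is invalid).
#' @export
inclination <- function(trunk, chair, neutral_index = NULL) {
  tq <- as_quat_matrix(trunk)
  cq <- as_quat_matrix(chair)
  n <- nrow(tq$q)
  if (nrow(cq$q) != n) stop("series must be equally long", call. = FALSE)
  valid <- stats::complete.cases(tq$q) & stats::complete.cases(cq$q)
  if (is.null(neutral_index)) neutral_index <- which(valid)[1]
  if (is.na(neutral_index) || neutral_index < 1 || neutral_index > n ||
      !valid[neutral_index]) {
    stop("neutral_index must point to a valid sample", call. = FALSE)
  }
  # q_rel = conj(q_chair) (x) q_trunk : trunk attitude in the chair frame
  qrel <- quat_rows_multiply(quat_rows_conjugate(cq$q), tq$q)
  q0 <- qrel[neutral_index, ]
  # D = conj(q_rel(neutral)) (x) q_rel(t)
  D <- quat_rows_multiply(matrix(quat_conjugate(q0), n, 4, byrow = TRUE), qrel)
  flip <- !is.na(D[, 1]) & D[, 1] < 0
  D[flip, ] <- -D[flip, ]
  vnorm <- sqrt(rowSums(D[, 2:4, drop = FALSE]^2))
  theta <- 2 * atan2(vnorm, D[, 1]) * 180 / pi
  # left-right axis of the chair expressed in the referencing frame
  y_ref <- as.numeric(quat_rows_rotate(
    matrix(quat_conjugate(q0), 1, 4), matrix(c(0, 1, 0), 1, 3)))
  proj <- (D[, 2] * y_ref[1] + D[, 3] * y_ref[2] + D[, 4] * y_ref[3])
  s <- ifelse(vnorm > 1e-12, sign(proj), 1)
  s[s == 0] <- 1
  angle <- theta * s
  angle[!valid] <- NA_real_
  angle[neutral_index] <- 0
  inclination_series(tq$time_s, angle)
}

#' Synchronize and re-reference an IMU and a reference inclination stream
#'
#' Computes the inclination of both systems, estimates their integer time
#' lag by cross-correlation of the two inclination series, crops both
#' orientation streams to the overlapping window, and recomputes both
#' inclination series against the same post-shift neutral sample, so that
#' all angles are relative to one neutral pose.
#'
#' @param imu_trunk,imu_chair `orientation_series` from the IMU route,
#'   resampled to `rate`.
#' @param ref_trunk,ref_chair `frame_series` (or `orientation_series`) from
#'   the reference route, resampled to `rate`.
#' @param rate common sample rate, Hz.
#' @param max_lag_s cross-correlation search window, seconds.
#' @return list with `imu` and `ref` (`inclination_series` on the common
#'   window) and `lag` (samples; positive when the reference stream started
#'   later than the IMU stream).
#' @export
resolve_sync <- function(imu_trunk, imu_chair, ref_trunk, ref_chair,
                         rate = 100, max_lag_s = 10) {
  incl_imu <- inclination(imu_trunk, imu_chair)
  incl_ref <- inclination(ref_trunk, ref_chair)
  lag <- sync_by_xcorr(incl_imu$angle_deg, incl_ref$angle_deg,
                       rate = rate, max_lag_s = max_lag_s)
  n_a <- nrow(incl_imu); n_b <- nrow(incl_ref)
  ia <- max(1L, 1L - lag):min(n_a, n_b - lag)
  if (length(ia) < 10 * rate) {
    stop("insufficient overlap after synchronization", call. = FALSE)
  }
  ib <- ia + lag
  sub_orient <- function(x, idx) {
    if (inherits(x, "orientation_series")) {
      orientation_series(x$time_s[idx] - x$time_s[idx[1]],
                         orientation_quats(x)[idx, , drop = FALSE],
                         x$beta[idx])
    } else {
      frame_series(x$time_s[idx] - x$time_s[idx[1]],
                   x$R[, , idx, drop = FALSE], x$valid[idx])
    }
  }
  it <- sub_orient(imu_trunk, ia); ic <- sub_orient(imu_chair, ia)
  rt <- sub_orient(ref_trunk, ib); rc <- sub_orient(ref_chair, ib)
  valid_imu <- stats::complete.cases(as_quat_matrix(it)$q) &
    stats::complete.cases(as_quat_matrix(ic)$q)
  valid_ref <- stats::complete.cases(as_quat_matrix(rt)$q) &
    stats::complete.cases(as_quat_matrix(rc)$q)
  neutral <- which(valid_imu & valid_ref)[1]
  if (is.na(neutral)) stop("no jointly valid sample for neutral pose", call. = FALSE)
  list(imu = inclination(it, ic, neutral_index = neutral),
       ref = inclination(rt, rc, neutral_index = neutral),
       lag = lag)
}
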