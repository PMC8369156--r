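# The gradient-descent complementary (Madgwick) MARG filter and the
# gyroscope-free earth-frame-only attitude estimator.
#
# Filter update, per sample t:
#
#   q_t = normalize( q_{t-1} + (dq_gyro - beta * dq_am) * dt )
#
# where dq_gyro = 0.5 * q (x) (0, omega) is the gyroscope quaternion rate
# and dq_am is one gradient-descent step of the accelerometer/magnetometer
# objective, normalized to unit magnitude so that the correction gain beta
# alone sets the correction size. beta is the filter's single tuning
# parameter; the adaptive extension supplies a per-sample beta schedule.

#' Filter configuration
#'
#' @param beta correction gain, dimensionless, `>= 0`. The widely used
#'   static-performance default is 0.033.
#' @param dt sample period in seconds, `> 0`.
#' @param q0 initial unit quaternion, or `NULL` to initialize from the
#'   earth-frame-only estimate of the first sample.
#' @return a `filter_config` list.
#' @export
filter_config <- function(beta = 0.033, dt = 0.01, q0 = NULL) {
  stopifnot(is.numeric(beta), all(beta >= 0), dt > 0)
  if (!is.null(q0)) q0 <- quat_normalize(q0)
  structure(list(beta = beta, dt = dt, q0 = q0), class = "filter_config")
}

#' One normalized gradient step of the MARG objective
#'
#' Evaluates the gradient of the six-dimensional objective aligning the
#' predicted gravity direction (earth reference `(0, 0, 1)`) and magnetic
#' field with the normalized accelerometer and magnetometer measurements.
#' The magnetic reference `b = (bx, 0, bz)` is rebuilt from the measured
#' field rotated into the earth frame with its horizontal component
#' collapsed onto the x axis (magnetic-distortion compensation). The
#' returned increment is normalized to unit magnitude; zero-norm sensor
#' input yields a zero increment with `degenerate = TRUE`, and a vanishing
#' gradient (stationary point) yields zero with `converged = TRUE`.
#'
#' @param q unit quaternion, current attitude.
#' @param accel numeric(3) accelerometer sample (any scale; normalized).
#' @param mag numeric(3) magnetometer sample (any scale; normalized).
#' @return list with `increment` (numeric(4), unit norm or zero),
#'   `degenerate`, `converged`, and `gradient_norm`.
#' @export
gradient_correction <- function(q, accel, mag) {
  assert_finite(q, "q")
  stopifnot(length(q) == 4, length(accel) == 3, length(mag) == 3)
  res <- mw_gradient_cpp(as.numeric(q), as.numeric(accel), as.numeric(mag))
  res$increment <- as.numeric(res$increment)
  res
}

#' One update of the complementary MARG filter
#'
#' @param q unit quaternion, attitude at the previous sample.
#' @param omega numeric(3) gyroscope sample, rad/s.
#' @param accel,mag numeric(3) accelerometer / magnetometer samples.
#' @param beta correction gain (`>= 0`).
#' @param dt step length, seconds (`> 0`).
#' @return list with `q` (updated unit quaternion) and `degenerate`
#'   (`TRUE` when accel/mag were unusable and a gyro-only step was taken).
#' @export
mw_update <- function(q, omega, accel, mag, beta, dt) {
  assert_finite(q, "q"); assert_finite(omega, "omega")
  stopifnot(beta >= 0)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a positive number", call. = FALSE)
  }
  res <- mw_step_cpp(as.numeric(q), as.numeric(omega), as.numeric(accel),
                     as.numeric(mag), beta, dt)
  res$q <- as.numeric(res$q)
  res
}

#' Run the complementary MARG filter over an IMU series
#'
#' Sequentially applies [mw_update()] with a constant gain or a per-sample
#' gain schedule, recording the gain used at every step. A constant
#' schedule reproduces the original fixed-gain filter on the identical
#' arithmetic path; an all-zero schedule reduces to pure gyroscope
#' integration.
#'
#' @param imu an `imu_series`.
#' @param beta scalar gain or numeric vector of length `nrow(imu)`.
#' @param q0 initial unit quaternion; defaults to the earth-frame-only
#'   estimate of the first sample (sessions start in a static pose).
#' @return an `orientation_series`.
#' @export
run_filter <- function(imu, beta = 0.033, q0 = NULL) {
  stopifnot(inherits(imu, "imu_series"))
  n <- nrow(imu)
  if (!length(beta) %in% c(1L, n)) {
    stop("beta must be scalar or one value per sample", call. = FALSE)
  }
  if (any(beta < 0)) stop("beta must be >= 0", call. = FALSE)
  beta <- if (length(beta) == 1L) rep(as.numeric(beta), n) else as.numeric(beta)
  gyro <- imu_matrix(imu, "gyro")
  accel <- imu_matrix(imu, "accel")
  mag <- imu_matrix(imu, "mag")
  if (is.null(q0)) {
    q0 <- earth_frame_only(accel[1, ], mag[1, ])
  } else {
    q0 <- quat_normalize(q0)
  }
  dt <- c(0, diff(imu$time_s))
  res <- mw_filter_cpp(gyro, accel, mag, beta, dt, q0)
  orientation_series(imu$time_s, res$q, beta, degenerate = res$degenerate)
}

#' Earth-frame-only attitude from one accelerometer/magnetometer pair
#'
#' Algebraic two-vector (TRIAD) attitude: the accelerometer direction is
#' taken as earth "up" (at rest the accelerometer reads +1 g opposite
#' gravity) and the magnetometer as "north". With `d = unit(-accel)` (earth
#' down in sensor axes), the triad `e = unit(d %x% m)`, `n = e %x% d`
#' yields the earth axes expressed in the sensor frame, assembled into the
#' sensor attitude in the package quaternion convention. No gyroscope data
#' are used; the estimate is exact for clean vectors and invalid under
#' linear acceleration or magnetic disturbance.
#'
#' @param accel numeric(3) accelerometer sample.
#' @param mag numeric(3) magnetometer sample; must not be parallel to
#'   `accel` (within 0.5 degrees).
#' @return unit quaternion.
#' @export
earth_frame_only <- function(accel, mag) {
  assert_finite(accel, "accel"); assert_finite(mag, "mag")
  an <- sqrt(sum(accel^2)); mn <- sqrt(sum(mag^2))
  if (an == 0 || mn == 0) stop("zero-norm accel or mag", call. = FALSE)
  d <- -accel / an
  m <- mag / mn
  e <- c(d[2] * m[3] - d[3] * m[2],
         d[3] * m[1] - d[1] * m[3],
         d[1] * m[2] - d[2] * m[1])
  en <- sqrt(sum(e^2))
  if (en < sin(0.5 * pi / 180)) {
    stop("accel and mag are (near-)parallel: attitude undefined", call. = FALSE)
  }
  e <- e / en
  nvec <- c(e[2] * d[3] - e[3] * d[2],
            e[3] * d[1] - e[1] * d[3],
            e[1] * d[2] - e[2] * d[1])
  # rows: earth axes (north, y = up x north, up) expressed in sensor axes
  R <- rbind(nvec, -e, -d)
  rotmat_to_quat(R)
}

#' Earth-frame-only attitude series
#'
#' Vectorized [earth_frame_only()] over all samples of an IMU series.
#' Samples with degenerate geometry get `NA` quaternions.
#'
#' @param imu an `imu_series`.
#' @return an `orientation_series` with `beta = NA` (no filtering involved).
#' @export
earth_frame_series <- function(imu) {
  stopifnot(inherits(imu, "imu_series"))
  A <- imu_matrix(imu, "accel")
  M <- imu_matrix(imu, "mag")
  an <- sqrt(rowSums(A^2)); mn <- sqrt(rowSums(M^2))
  D <- -A / an
  Mu <- M / mn
  E <- cbind(D[, 2] * Mu[, 3] - D[, 3] * Mu[, 2],
             D[, 3] * Mu[, 1] - D[, 1] * Mu[, 3],
             D[, 1] * Mu[, 2] - D[, 2] * Mu[, 1])
  en <- sqrt(rowSums(E^2))
  bad <- !is.finite(en) | en < sin(0.5 * pi / 180)
  E <- E / en
  N <- cbind(E[, 2] * D[, 3] - E[, 3] * D[, 2],
             E[, 3] * D[, 1] - E[, 1] * D[, 3],
             E[, 1] * D[, 2] - E[, 2] * D[, 1])
  n <- nrow(A)
  Q <- matrix(NA_real_, n, 4)
  for (i in seq_len(n)) {
    if (bad[i]) next
    Q[i, ] <- rotmat_to_quat(rbind(N[i, ], -E[i, ], -D[i, ]))
  }
  orientation_series(imu$time_s, Q, beta = NA_real_)
}
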