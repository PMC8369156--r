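# Independent oracles used across the suite. Everything here is written
# from first principles (closed forms, finite differences, a line-by-line
# transliteration of the published gradient-descent MARG filter) and never
# calls the package's own hot paths it is checking.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# closed-form axis-angle constructions
aa_quat <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  a <- deg2rad(angle_deg) / 2
  c(cos(a), sin(a) * axis)
}

aa_matrix <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  a <- deg2rad(angle_deg)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

random_unit_quat <- function() {
  q <- stats::rnorm(4)
  q / sqrt(sum(q^2))
}

# angle (degrees) between two unit quaternions, sign-insensitive; the
# chord-based form keeps full precision for tiny angles (acos loses
# ~sqrt(eps) there)
quat_angle_deg <- function(a, b) {
  d <- min(sqrt(sum((a - b)^2)), sqrt(sum((a + b)^2)))
  rad2deg(4 * asin(min(1, d / 2)))
}

# angle between rows of two n x 4 quaternion matrices
quat_rows_angle_deg <- function(A, B) {
  d <- pmin(sqrt(rowSums((A - B)^2)), sqrt(rowSums((A + B)^2)))
  rad2deg(4 * asin(pmin(1, d / 2)))
}

# --- MARG objective and its numerical gradient -------------------------------
# The six-dimensional objective of the gradient-descent filter: predicted
# minus measured gravity and magnetic-field directions in the sensor frame.
marg_objective <- function(q, accel, mag) {
  a <- accel / sqrt(sum(accel^2))
  m <- mag / sqrt(sum(mag^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)
  ), 3, 3, byrow = TRUE)
  h <- R %*% m
  b <- c(sqrt(h[1]^2 + h[2]^2), 0, h[3])
  f_g <- t(R) %*% c(0, 0, 1) - a
  f_b <- t(R) %*% b - m
  c(f_g, f_b)
}

marg_objective_norm2 <- function(q, accel, mag) sum(marg_objective(q, accel, mag)^2)

# central-difference gradient of 0.5 * |F|^2 with the reference field
# treated as fixed at q (as the filter does within one step)
marg_gradient_numeric <- function(q, accel, mag, h = 1e-7) {
  a <- accel / sqrt(sum(accel^2))
  m <- mag / sqrt(sum(mag^2))
  # freeze b at the current q
  R <- quat_to_rotmat(q / sqrt(sum(q^2)))
  hv <- R %*% m
  b <- c(sqrt(hv[1]^2 + hv[2]^2), 0, hv[3])
  obj <- function(qq) {
    Rq <- matrix(c(
      1 - 2 * (qq[3]^2 + qq[4]^2), 2 * (qq[2] * qq[3] - qq[1] * qq[4]), 2 * (qq[2] * qq[4] + qq[1] * qq[3]),
      2 * (qq[2] * qq[3] + qq[1] * qq[4]), 1 - 2 * (qq[2]^2 + qq[4]^2), 2 * (qq[3] * qq[4] - qq[1] * qq[2]),
      2 * (qq[2] * qq[4] - qq[1] * qq[3]), 2 * (qq[3] * qq[4] + qq[1] * qq[2]), 1 - 2 * (qq[2]^2 + qq[3]^2)
    ), 3, 3, byrow = TRUE)
    0.5 * sum((t(Rq) %*% c(0, 0, 1) - a)^2) + 0.5 * sum((t(Rq) %*% b - m)^2)
  }
  g <- numeric(4)
  for (i in 1:4) {
    e <- numeric(4); e[i] <- h
    g[i] <- (obj(q + e) - obj(q - e)) / (2 * h)
  }
  g
}

# --- reference transliteration of the published MARG filter ------------------
# Step-by-step scalar implementation of the gradient-descent update with
# normalized correction, kept deliberately naive and independent of the
# package's compiled path.
reference_mw_step <- function(q, gyro, accel, mag, beta, dt) {
  q1 <- q[1]; q2 <- q[2]; q3 <- q[3]; q4 <- q[4]
  an <- sqrt(sum(accel^2)); mn <- sqrt(sum(mag^2))
  if (an == 0 || mn == 0) {
    qdot <- 0.5 * quat_multiply(q, c(0, gyro))
    qn <- q + qdot * dt
    return(qn / sqrt(sum(qn^2)))
  }
  ax <- accel[1] / an; ay <- accel[2] / an; az <- accel[3] / an
  mx <- mag[1] / mn; my <- mag[2] / mn; mz <- mag[3] / mn

  h <- quat_multiply(quat_multiply(q, c(0, mx, my, mz)), quat_conjugate(q))
  bx <- sqrt(h[2]^2 + h[3]^2); bz <- h[4]

  F <- c(
    2 * (q2 * q4 - q1 * q3) - ax,
    2 * (q1 * q2 + q3 * q4) - ay,
    2 * (0.5 - q2^2 - q3^2) - az,
    2 * bx * (0.5 - q3^2 - q4^2) + 2 * bz * (q2 * q4 - q1 * q3) - mx,
    2 * bx * (q2 * q3 - q1 * q4) + 2 * bz * (q1 * q2 + q3 * q4) - my,
    2 * bx * (q1 * q3 + q2 * q4) + 2 * bz * (0.5 - q2^2 - q3^2) - mz
  )
  J <- matrix(c(
    -2 * q3, 2 * q4, -2 * q1, 2 * q2,
    2 * q2, 2 * q1, 2 * q4, 2 * q3,
    0, -4 * q2, -4 * q3, 0,
    -2 * bz * q3, 2 * bz * q4, -4 * bx * q3 - 2 * bz * q1, -4 * bx * q4 + 2 * bz * q2,
    -2 * bx * q4 + 2 * bz * q2, 2 * bx * q3 + 2 * bz * q1, 2 * bx * q2 + 2 * bz * q4, -2 * bx * q1 + 2 * bz * q3,
    2 * bx * q3, 2 * bx * q4 - 4 * bz * q2, 2 * bx * q1 - 4 * bz * q3, 2 * bx * q2
  ), 6, 4, byrow = TRUE)
  grad <- as.numeric(t(J) %*% F)
  gn <- sqrt(sum(grad^2))
  qdot <- 0.5 * quat_multiply(q, c(0, gyro))
  if (gn > 1e-12) qdot <- qdot - beta * grad / gn
  qn <- q + qdot * dt
  qn / sqrt(sum(qn^2))
}

reference_mw_filter <- function(imu, beta, q0) {
  gyro <- imu_matrix(imu, "gyro")
  accel <- imu_matrix(imu, "accel")
  mag <- imu_matrix(imu, "mag")
  n <- nrow(imu)
  dt <- diff(imu$time_s)
  Q <- matrix(NA_real_, n, 4)
  Q[1, ] <- q0
  q <- q0
  for (k in 2:n) {
    q <- reference_mw_step(q, gyro[k, ], accel[k, ], mag[k, ], beta, dt[k - 1])
    Q[k, ] <- q
  }
  Q
}

# static truth-consistent IMU series: attitude q_true, clean sensors
static_imu <- function(q_true, n = 1001, rate = 100,
                       mag_earth = c(0.45, 0, -0.75)) {
  Rq <- quat_to_rotmat(q_true)
  accel <- as.numeric(t(Rq) %*% c(0, 0, 1))
  mag <- as.numeric(t(Rq) %*% mag_earth)
  imu_series(seq(0, (n - 1) / rate, by = 1 / rate),
             matrix(0, n, 3),
             matrix(accel, n, 3, byrow = TRUE),
             matrix(mag, n, 3, byrow = TRUE))
}
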