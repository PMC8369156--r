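mag_earth <- c(0.45, 0, -0.75)

test_that("gradient step: stationary point, unit norm, numeric gradient", {
  # consistent reference pose: zero objective, converged flag
  g0 <- gradient_correction(c(1, 0, 0, 0), c(0, 0, 1), c(0.45, 0, -0.75))
  expect_true(g0$converged)
  expect_equal(g0$increment, c(0, 0, 0, 0))

  set.seed(31)
  for (i in 1:15) {
    q <- random_unit_quat()
    q_true <- random_unit_quat()
    Rt <- quat_to_rotmat(q_true)
    accel <- as.numeric(t(Rt) %*% c(0, 0, 1))
    mag <- as.numeric(t(Rt) %*% mag_earth)
    g <- gradient_correction(q, accel, mag)
    expect_false(g$degenerate)
    if (g$gradient_norm > 1e-9) {
      # normalized to unit magnitude
      expect_equal(sqrt(sum(g$increment^2)), 1, tolerance = 1e-12)
      # direction agrees with the finite-difference gradient of the objective
      gn <- marg_gradient_numeric(q, accel, mag)
      expect_equal(g$increment, gn / sqrt(sum(gn^2)), tolerance = 1e-5)
    }
  }

  # zero-norm input: degenerate flag and zero increment
  gd <- gradient_correction(c(1, 0, 0, 0), c(0, 0, 0), mag_earth)
  expect_true(gd$degenerate)
  expect_equal(gd$increment, c(0, 0, 0, 0))
})

test_that("repeated small gradient steps decrease the objective", {
  set.seed(32)
  q_true <- random_unit_quat()
  Rt <- quat_to_rotmat(q_true)
  accel <- as.numeric(t(Rt) %*% c(0, 0, 1))
  mag <- as.numeric(t(Rt) %*% mag_earth)
  q <- quat_normalize(q_true + 0.2 * stats::rnorm(4))
  trace <- marg_objective_norm2(q, accel, mag)
  for (i in 1:300) {
    g <- gradient_correction(q, accel, mag)
    q <- quat_normalize(q - 2e-3 * g$increment)
    trace <- c(trace, marg_objective_norm2(q, accel, mag))
  }
  # fixed-length normalized steps dither near the optimum, so require a
  # strict decrease across coarse checkpoints until the floor is reached
  cp <- trace[c(1, 50, 100, 150)]
  expect_true(all(diff(cp) < 0))
  expect_lt(min(trace), 1e-4)
  expect_lt(trace[301], trace[1] / 20)
})

test_that("single update: gyro-only reduction and static convergence", {
  q <- random_unit_quat()
  # beta = 0, omega = 0: unchanged
  expect_equal(mw_update(q, c(0, 0, 0), c(0, 0, 1), mag_earth, 0, 0.01)$q, q,
               tolerance = 1e-15)
  # beta = 0 matches gyroscope integration exactly
  omega <- c(0.4, -0.2, 0.9)
  expect_equal(mw_update(q, omega, c(0, 0, 1), mag_earth, 0, 0.01)$q,
               integrate_gyro(q, omega, 0.01), tolerance = 1e-15)
  # degenerate accel: gyro-only step with flag
  up <- mw_update(q, omega, c(0, 0, 0), mag_earth, 0.1, 0.01)
  expect_true(up$degenerate)
  expect_equal(up$q, integrate_gyro(q, omega, 0.01), tolerance = 1e-15)

  # static truth-consistent input, 20 degrees off, beta 0.033 at 100 Hz:
  # error decreases monotonically (coarsely) and ends below 0.5 degrees
  imu <- static_imu(c(1, 0, 0, 0), n = 1001)
  q0 <- aa_quat(c(1, 0.3, 0), 20)
  out <- orientation_quats(run_filter(imu, 0.033, q0 = q0))
  err <- quat_rows_angle_deg(out, matrix(c(1, 0, 0, 0), 1001, 4, byrow = TRUE))
  expect_lt(err[1001], 0.5)
  checkpoints <- err[seq(1, 1001, by = 100)]
  expect_true(all(diff(checkpoints) < 0.05))
})

test_that("filter over a series: schedules, provenance and reductions", {
  set.seed(33)
  n <- 400
  t <- seq(0, (n - 1) * 0.01, by = 0.01)
  imu <- imu_series(t, matrix(stats::rnorm(n * 3, 0, 0.4), n, 3),
                    matrix(rep(c(0, 0, 1), each = n), n, 3) + stats::rnorm(n * 3, 0, 0.02),
                    matrix(rep(mag_earth, each = n), n, 3) + stats::rnorm(n * 3, 0, 0.02))
  q0 <- c(1, 0, 0, 0)

  # constant schedule is bit-identical to the scalar-gain filter
  a <- run_filter(imu, 0.033, q0 = q0)
  b <- run_filter(imu, rep(0.033, n), q0 = q0)
  expect_identical(orientation_quats(a), orientation_quats(b))

  # all-zero schedule = pure gyro integration
  z <- orientation_quats(run_filter(imu, 0, q0 = q0))
  q <- q0
  for (k in 2:n) q <- integrate_gyro(q, as.numeric(imu[k, 2:4]), 0.01)
  expect_equal(unname(z[n, ]), q, tolerance = 1e-12)

  # alternating schedule: per-sample gain provenance equals the input
  sched <- rep(c(0.9635, 0.0015), length.out = n)
  s <- run_filter(imu, sched, q0 = q0)
  expect_identical(s$beta, sched)

  expect_error(run_filter(imu, c(0.1, 0.2)), "per sample")
})

test_that("filter agrees with an independent transliteration of the published algorithm", {
  # 60 s of noisy, slowly rotating 100 Hz data
  set.seed(34)
  n <- 6001
  t <- seq(0, 60, by = 0.01)
  ang <- 0.5 * sin(2 * pi * 0.1 * t)
  gyro <- cbind(0.5 * 2 * pi * 0.1 * cos(2 * pi * 0.1 * t), 0, 0) +
    matrix(stats::rnorm(n * 3, 0, 0.01), n, 3)
  accel <- t(sapply(ang, function(a) as.numeric(t(aa_matrix(c(1, 0, 0), rad2deg(a))) %*% c(0, 0, 1)))) +
    matrix(stats::rnorm(n * 3, 0, 0.01), n, 3)
  mag <- t(sapply(ang, function(a) as.numeric(t(aa_matrix(c(1, 0, 0), rad2deg(a))) %*% mag_earth))) +
    matrix(stats::rnorm(n * 3, 0, 0.01), n, 3)
  imu <- imu_series(t, gyro, accel, mag)
  q0 <- earth_frame_only(accel[1, ], mag[1, ])
  mine <- orientation_quats(run_filter(imu, 0.033, q0 = q0))
  ref <- reference_mw_filter(imu, 0.033, q0)
  expect_lt(max(quat_rows_angle_deg(mine, ref)), 0.1)
})

test_that("earth-frame-only attitude: recovery, tilt geometry, degeneracy", {
  expect_equal(earth_frame_only(c(0, 0, 1), c(0.45, 0, -0.75)), c(1, 0, 0, 0),
               tolerance = 1e-12)
  set.seed(35)
  for (i in 1:50) {
    q <- random_unit_quat()
    Rt <- quat_to_rotmat(q)
    est <- earth_frame_only(as.numeric(t(Rt) %*% c(0, 0, 1)),
                            as.numeric(t(Rt) %*% mag_earth))
    expect_lt(quat_angle_deg(est, q), 1e-6)   # degrees
  }
  # planted tilt: accel direction tilted by phi from a reference pose gives
  # an attitude phi away from identity
  for (phi in c(5, 15, 30)) {
    a <- c(sin(deg2rad(phi)), 0, cos(deg2rad(phi)))
    est <- earth_frame_only(a, mag_earth)
    expect_equal(quat_angle_deg(est, c(1, 0, 0, 0)), phi, tolerance = 1e-6)
  }
  expect_error(earth_frame_only(c(0, 0, 1), c(0, 0, 2)), "parallel")
  expect_error(earth_frame_only(c(0, 0, 0), mag_earth), "zero-norm")
})

test_that("unit norm is preserved over long runs", {
  set.seed(36)
  n <- 20000
  imu <- imu_series(seq(0, (n - 1) * 0.01, 0.01),
                    matrix(stats::rnorm(n * 3, 0, 1), n, 3),
                    matrix(rep(c(0, 0, 1), each = n), n, 3) + stats::rnorm(n * 3, 0, 0.05),
                    matrix(rep(mag_earth, each = n), n, 3) + stats::rnorm(n * 3, 0, 0.05))
  Q <- orientation_quats(run_filter(imu, 0.1))
  expect_lt(max(abs(sqrt(rowSums(Q^2)) - 1)), 1e-9)
})

test_that("steady-state error under constant gyro bias decreases with the gain", {
  # constant bias pulls the attitude away; the earth-frame correction
  # counteracts it more strongly for larger gains
  n <- 3001
  imu <- static_imu(c(1, 0, 0, 0), n = n)
  gyro <- imu_matrix(imu, "gyro") + matrix(rep(c(0.01, 0, 0), each = n), n, 3)
  imu_b <- imu_series(imu$time_s, gyro, imu_matrix(imu, "accel"), imu_matrix(imu, "mag"))
  err <- sapply(c(0.001, 0.002, 0.004, 0.01), function(beta) {
    Q <- orientation_quats(run_filter(imu_b, beta, q0 = c(1, 0, 0, 0)))
    # mean attitude over the steady window (averaging removes the
    # fixed-step dither and leaves the systematic offset)
    qm <- colMeans(Q[2500:n, , drop = FALSE])
    quat_angle_deg(qm / sqrt(sum(qm^2)), c(1, 0, 0, 0))
  })
  # below saturation the equilibrium error shrinks as the gain grows ...
  expect_true(all(diff(err) < 0))
  # ... and once the fixed-size correction outpaces the drift the bias is
  # rejected to a fraction of a degree for any larger gain
  for (beta in c(0.1, 0.5)) {
    Q <- orientation_quats(run_filter(imu_b, beta, q0 = c(1, 0, 0, 0)))
    qm <- colMeans(Q[2500:n, , drop = FALSE])
    expect_lt(quat_angle_deg(qm / sqrt(sum(qm^2)), c(1, 0, 0, 0)), 0.1)
  }
})
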