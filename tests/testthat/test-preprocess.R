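sphere_points <- function(n, center, r = 1, seed = 1) {
  set.seed(seed)
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  sweep(r * u, 2, center, "+")
}

test_that("hard-iron offset: sphere fit, fallback and idempotence", {
  pts <- sphere_points(300, c(10, -5, 3), r = 0.9)
  fit <- correct_hard_iron(pts)
  expect_equal(fit$offset, c(10, -5, 3), tolerance = 1e-6)
  expect_false(fit$fallback)

  fit0 <- correct_hard_iron(sphere_points(300, c(0, 0, 0)))
  expect_equal(fit0$offset, c(0, 0, 0), tolerance = 1e-6)

  # corrected norms are more uniform than raw when an offset exists
  cv <- function(x) stats::sd(x) / mean(x)
  raw_norm <- sqrt(rowSums(pts^2))
  cor_norm <- sqrt(rowSums(fit$corrected^2))
  expect_lt(cv(cor_norm), cv(raw_norm))

  # identical points: degenerate coverage -> midpoint fallback with warning
  same <- matrix(rep(c(1, 2, 3), each = 50), 50, 3)
  expect_warning(fb <- correct_hard_iron(same), "degenerate")
  expect_true(fb$fallback)
  expect_equal(fb$offset, c(1, 2, 3))

  # idempotence on sphere-distributed data
  fit2 <- correct_hard_iron(fit$corrected)
  expect_lt(max(abs(fit2$offset)), 1e-6)
})

test_that("spline resampling: analytic sinusoid, identity and ramps", {
  t120 <- seq(0, 5, by = 1 / 120)
  sig <- function(t) sin(2 * pi * 2 * t)
  imu <- imu_series(t120, matrix(sig(t120), length(t120), 3),
                    matrix(sig(t120), length(t120), 3),
                    matrix(sig(t120), length(t120), 3))
  rs <- resample_to(imu, 100)
  expect_equal(diff(rs$time_s), rep(0.01, nrow(rs) - 1), tolerance = 1e-9)
  inner <- rs$time_s > 0.1 & rs$time_s < 4.9
  expect_lt(max(abs(rs$gyro_x[inner] - sig(rs$time_s[inner]))), 1e-4)

  # already-uniform 100 Hz input is returned unchanged
  t100 <- seq(0, 2, by = 0.01)
  imu2 <- imu_series(t100, matrix(1, length(t100), 3),
                     matrix(2, length(t100), 3), matrix(3, length(t100), 3))
  rs2 <- resample_to(imu2, 100)
  expect_equal(as.data.frame(rs2), as.data.frame(imu2), tolerance = 1e-9)

  # jittered timestamps of a linear ramp resample to the exact ramp
  set.seed(3)
  tj <- sort(seq(0, 2, by = 0.01) + c(0, stats::rnorm(200, 0, 1e-3)))
  imu3 <- imu_series(tj, matrix(2 * tj, 201, 3), matrix(-tj, 201, 3),
                     matrix(tj, 201, 3))
  rs3 <- resample_to(imu3, 100)
  expect_equal(rs3$gyro_x, 2 * rs3$time_s, tolerance = 1e-9)

  expect_error(imu_series(c(0, 0.01, 0.01), matrix(0, 3, 3),
                          matrix(0, 3, 3), matrix(0, 3, 3)), "increasing")

  # mean of a band-limited signal is preserved
  expect_equal(mean(rs$gyro_x[inner]), mean(sig(rs$time_s[inner])),
               tolerance = 1e-3)
})

test_that("gap interpolation fills only short interior gaps", {
  t <- seq(0, 2, by = 1 / 120)
  pos <- cbind(3 * t, -t, 5 + t)
  colnames(pos) <- c("marker1_x", "marker1_y", "marker1_z")
  full <- marker_series(t, pos)

  # 0.1 s interior gap in a linear trajectory -> filled exactly
  gap <- which(t > 1 & t < 1.1)
  holey <- pos; holey[gap, ] <- NA
  filled <- interpolate_gaps(marker_series(t, holey))
  expect_false(anyNA(as.matrix(filled[, -1])))
  expect_equal(as.matrix(filled[, -1]), pos, tolerance = 1e-9,
               ignore_attr = TRUE)

  # 0.5 s gap stays missing
  gap2 <- which(t > 0.5 & t < 1.0)
  holey2 <- pos; holey2[gap2, ] <- NA
  kept <- interpolate_gaps(marker_series(t, holey2))
  expect_true(all(is.na(as.matrix(kept[gap2, -1]))))

  # no gaps: identity
  expect_equal(as.data.frame(interpolate_gaps(full)), as.data.frame(full))

  # boundary gap is never extrapolated
  holey3 <- pos; holey3[1:3, ] <- NA
  expect_true(all(is.na(as.matrix(interpolate_gaps(marker_series(t, holey3))[1:3, -1]))))
})

rigid_markers <- function(t, R = diag(3), translate = c(0, 0, 0), extra = NULL) {
  geom <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 80, 0))
  if (!is.null(extra)) geom <- rbind(geom, extra)
  P <- matrix(NA_real_, length(t), 3 * nrow(geom))
  for (j in seq_len(nrow(geom))) {
    P[, (3 * j - 2):(3 * j)] <- matrix(as.numeric(R %*% geom[j, ]) + translate,
                                       length(t), 3, byrow = TRUE)
  }
  marker_series(t, P)
}

test_that("cluster frames: rigid rotation recovery and marker selection", {
  t <- seq(0, 1, by = 0.01)
  rest <- build_cluster_frames(rigid_markers(t))
  expect_true(all(rest$valid))
  # constant frame over time
  expect_lt(max(abs(rest$R[, , 1] - rest$R[, , length(t)])), 1e-12)

  R <- aa_matrix(c(0.3, -1, 0.5), 40)
  rot <- build_cluster_frames(rigid_markers(t, R = R))
  expect_equal(rot$R[, , 5], R %*% rest$R[, , 5], tolerance = 1e-9)

  # global translation does not change the frames
  shifted <- build_cluster_frames(rigid_markers(t, translate = c(500, -200, 90)))
  expect_equal(shifted$R[, , 10], rest$R[, , 10], tolerance = 1e-12)

  # a 4th marker with missing samples is avoided by the selection rule
  ms <- rigid_markers(t, extra = c(50, 40, 30))
  m <- as.matrix(ms[, -1])
  m[10:30, 10:12] <- NA
  sel <- build_cluster_frames(marker_series(t, m))
  expect_true(all(sel$valid))

  # collinear markers invalidate the sample
  bad <- rigid_markers(t, extra = NULL)
  mb <- as.matrix(bad[, -1])
  mb[7, 7:9] <- 2 * mb[7, 4:6]  # marker3 on the line of marker2
  col <- build_cluster_frames(marker_series(t, mb))
  expect_false(col$valid[7])
})

test_that("cross-correlation synchronization recovers constructed lags", {
  set.seed(21)
  t <- seq(0, 30, by = 0.01)
  a <- sin(2 * pi * 0.3 * t) + 0.3 * sin(2 * pi * 0.11 * t) + stats::rnorm(length(t), 0, 0.02)
  expect_identical(sync_by_xcorr(a, a), 0L)
  for (lag in c(17L, -60L, 200L, -200L)) {
    b <- if (lag >= 0) c(rep(a[1], lag), a[seq_len(length(a) - lag)]) else
      c(a[(1 - lag):length(a)], rep(a[length(a)], -lag))
    expect_identical(sync_by_xcorr(a, b), lag)
  }
  expect_error(sync_by_xcorr(rep(1, 3000), a), "constant")

  # anti-phase sinusoids of period 100 samples: tie at +-50 broken to -50
  s <- sin(2 * pi * seq_len(3000) / 100)
  expect_identical(sync_by_xcorr(s, -s), -50L)
})
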