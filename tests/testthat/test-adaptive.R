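test_that("neutral-window noise estimate", {
  t <- seq(0, 30, by = 0.01)
  a <- inclination_series(t, rep(0, length(t)))
  expect_equal(estimate_noise(a, a), 0)

  # white noise of known SD recovered within sampling error at n = 2000
  set.seed(51)
  noise <- stats::rnorm(2001, 0, 1.3)
  b <- inclination_series(t[1:2001], noise)
  z <- inclination_series(t[1:2001], rep(0, 2001))
  expect_equal(estimate_noise(b, z), 1.3, tolerance = 0.1)

  # a constant offset does not contribute to the standard deviation
  cshift <- inclination_series(t, rep(5, length(t)))
  expect_equal(estimate_noise(cshift, a), 0)

  expect_error(estimate_noise(inclination_series(t[1:100], rep(0, 100)),
                              inclination_series(t[1:100], rep(0, 100))),
               "shorter")

  # cohort variant is the mean of the per-subject estimates
  pairs <- list(list(ef = b, ref = z), list(ef = z[1:2001, ], ref = z[1:2001, ]))
  expect_equal(estimate_noise_mean(pairs),
               estimate_noise(b, z) / 2, tolerance = 1e-12)
})

test_that("trust labels match hand-computed vectors and the S5 rule", {
  d <- c(0.1, 0.5, 3.0, 0.2, 0.4)
  lab <- make_labels(d, rep(0, 5), threshold_deg = 2.27)
  expect_identical(lab$efcorrect, c(1L, 1L, 0L, 1L, 1L))
  expect_identical(lab$efcorrect_s5, c(0L, 0L, 0L, 0L, 0L))

  # identical series: all trusted under both variants
  same <- make_labels(rep(1, 9), rep(1, 9), threshold_deg = 2)
  expect_true(all(same$efcorrect == 1L))
  expect_true(all(same$efcorrect_s5 == 1L))

  # a difference exactly at the threshold is incorrect (strict inequality)
  expect_identical(make_labels(2.27, 0, threshold_deg = 2.27)$efcorrect, 0L)

  # truncated boundary windows: an isolated middle outlier clears S5 only
  # beyond two samples away
  d2 <- c(0, 0, 0, 0, 9, 0, 0, 0, 0)
  lab2 <- make_labels(d2, rep(0, 9), threshold_deg = 1)
  expect_identical(lab2$efcorrect_s5, c(1L, 1L, 0L, 0L, 0L, 0L, 0L, 1L, 1L))

  expect_error(make_labels(1:3, 1:4, 1), "aligned")
})

test_that("the S5 label implies the plain label on random inputs", {
  set.seed(52)
  d <- abs(stats::rnorm(1e5, 0, 2))
  lab <- make_labels(d, rep(0, 1e5), threshold_deg = 2.27)
  expect_true(all(lab$efcorrect[lab$efcorrect_s5 == 1L] == 1L))
})

test_that("prediction decoding into the gain schedule", {
  cfg <- adaptive_config()
  expect_equal(decode_beta(rep(1, 5), cfg), rep(0.9635, 5))
  expect_equal(decode_beta(rep(0, 5), cfg), rep(0.0015, 5))
  expect_equal(decode_beta(c(1, 0, 1), cfg), c(0.9635, 0.0015, 0.9635))
  expect_error(decode_beta(c(1, 2, 0), cfg), "binary")
  expect_error(adaptive_config(beta_high = 0.1, beta_low = 0.5), "beta_low")
})

test_that("constant predictions reduce the adaptive run to the fixed-gain filter", {
  s <- generate_session(session_config(seed = 15))
  imu_t <- resample_to(s$imu_trunk); imu_c <- resample_to(s$imu_chair)
  cfg <- adaptive_config()
  always1 <- function(features) rep(1, nrow(features))
  always0 <- function(features) rep(0, nrow(features))

  ext1 <- run_extended(imu_t, imu_c, always1, cfg)
  expect_identical(orientation_quats(ext1$trunk),
                   orientation_quats(run_filter(imu_t, cfg$beta_high)))
  ext0 <- run_extended(imu_t, imu_c, always0, cfg)
  expect_identical(orientation_quats(ext0$chair),
                   orientation_quats(run_filter(imu_c, cfg$beta_low)))
  expect_equal(ext1$beta, rep(cfg$beta_high, nrow(imu_t)))

  expect_error(run_extended(imu_t, imu_c, function(f) rep(2, nrow(f))), "binary")
})

test_that("gain grid search: dimensions, plateau rule and static sanity", {
  # static, clean session with all-trusted labels: RMSE is non-increasing
  # in beta_high along the first row (faster drift rejection, no dynamics)
  cfg <- zero_noise_config(session_config(
    plan = data.frame(kind = "static_neutral", duration = 25),
    time_offset = 0))
  cfg$gyro_bias0_sd <- 0.01
  s <- generate_session(cfg)
  imu_t <- resample_to(s$imu_trunk); imu_c <- resample_to(s$imu_chair)
  # bias is deliberately left uncorrected here to create drift
  n <- nrow(imu_t)
  gyro_b <- imu_matrix(imu_t, "gyro") + matrix(rep(c(0.012, 0.005, -0.008), each = n), n, 3)
  imu_tb <- imu_series(imu_t$time_s, gyro_b, imu_matrix(imu_t, "accel"),
                       imu_matrix(imu_t, "mag"))
  sess <- list(list(imu_trunk = imu_tb, imu_chair = imu_c,
                    labels = rep(1, n),
                    ref = inclination_series(imu_t$time_s, rep(0, n)),
                    neutral_index = 1))
  # gains chosen below the saturation point (correction capacity under the
  # drift rate), where faster correction strictly helps
  g <- grid_search_beta(sess, beta_low_grid = 0,
                        beta_high_grid = c(0.002, 0.004, 0.006, 0.008, 0.01))
  expect_equal(dim(g$surface), c(1L, 5L))
  expect_true(all(diff(as.numeric(g$surface)) < 0))

  # full default grid dimensions: 11 x 21 = 231 combinations
  expect_length(seq(0, 0.01, by = 0.001), 11)
  expect_length(seq(0.5, 1, by = 0.025), 21)

  expect_error(grid_search_beta(list()), "empty")
})

test_that("label fraction falls as the disturbance magnitude grows", {
  fracs <- sapply(c(0.15, 0.6, 2), function(scale) {
    cfg <- session_config(seed = 77)
    # one disturbance level scales everything that corrupts the
    # earth-frame estimate: movement vigour, push pulses, field episodes
    cfg$trunk_amp_deg <- cfg$trunk_amp_deg * scale
    cfg$accel_pulse_g <- cfg$accel_pulse_g * scale
    cfg$mag_disturb_mag <- cfg$mag_disturb_mag * scale
    # fixed threshold so only the disturbance level varies
    p <- prepare_session(generate_session(cfg), threshold_deg = 2)
    mean(p$labels$efcorrect)
  })
  expect_true(all(diff(fracs) < 0))
})
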