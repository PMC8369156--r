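# Seeded generator of synthetic two-sensor wheelchair-sport sessions with
# ground-truth orientations. The generator emulates the signal structure
# the adaptive filter is designed for -- static neutral stretches, isolated
# trunk rotations, acceleration-rich sprints with push-locked trunk lean,
# turns, magnetic-disturbance episodes, gyroscope bias drift, hard-iron
# offsets, sensor noise, marker noise and occlusion gaps, differing sample
# rates and an unknown inter-system time offset -- not wheelchair vehicle
# physics. Ground-truth trajectories are smooth splines through per-segment
# keyframes.

segment_kinds <- c("static_neutral", "trunk_rotations", "sprint", "turn",
                   "collision", "ball_handling")

#' Default session segment plan
#'
#' A static neutral pose long enough for the 20 s noise window, isolated
#' trunk rotations, two sprints, a turn, and a closing static stretch.
#'
#' @return data.frame with columns `kind` and `duration` (seconds).
#' @export
default_plan <- function() {
  data.frame(
    kind = c("static_neutral", "trunk_rotations", "sprint", "turn",
             "sprint", "static_neutral"),
    duration = c(22, 12, 10, 8, 10, 8)
  )
}

#' Synthetic session configuration
#'
#' All noise magnitudes default to values typical of consumer-grade sports
#' IMUs and optical capture: gyroscope noise 0.003 rad/s with a constant
#' bias of ~0.3 deg/s plus random-walk drift, accelerometer noise 0.004 g,
#' sprint push pulses of 0.45 g peak, magnetometer noise 0.003 (arbitrary
#' field units, earth field magnitude ~0.87), hard-iron offset of a few
#' tenths, episodic wheelchair-fixed magnetic disturbance up to 0.3 during
#' dynamic segments, marker noise 0.25 mm, occasional occlusion gaps, and
#' mounting misalignments of a few degrees between sensor and segment.
#'
#' @param plan segment plan (data.frame `kind`, `duration`).
#' @param imu_rate,mocap_rate sample rates, Hz.
#' @param time_offset IMU recording start relative to the optical system,
#'   seconds (`>= 0`).
#' @param imu_jitter_sd timestamp jitter SD of the IMU clock, seconds.
#' @param gyro_noise_sd gyroscope white noise SD, rad/s.
#' @param gyro_bias0_sd SD of the constant gyroscope bias, rad/s.
#' @param gyro_bias_walk_sd gyroscope bias random-walk SD, rad/s per sqrt s.
#' @param accel_noise_sd accelerometer white noise SD, g.
#' @param accel_pulse_g peak linear-acceleration pulse during sprints, g.
#' @param mag_noise_sd magnetometer white noise SD, field units.
#' @param hard_iron numeric(3) hard-iron offset added to both sensors.
#' @param hard_iron_trunk,hard_iron_chair per-sensor overrides of
#'   `hard_iron` (the trunk device is shared equipment with a fixed offset;
#'   wheelchairs, and hence the chair-sensor environment, differ).
#' @param mag_disturb_mag peak magnetic-disturbance magnitude, field units.
#' @param mag_disturb_rate disturbance episodes per second inside dynamic
#'   segments (episodes last 1-3 s; the field is clean in between).
#' @param marker_noise_mm optical marker noise SD, mm.
#' @param occlusion_rate expected occlusion gaps per marker per second.
#' @param occlusion_gap_mean mean occlusion gap length, seconds.
#' @param mounting_deg_trunk,mounting_deg_chair sensor-to-segment mounting
#'   rotation magnitude, degrees (random axis).
#' @param trunk_amp_deg trunk-rotation amplitude, degrees.
#' @param push_rate_hz sprint push cadence, Hz.
#' @param subject_id subject identifier.
#' @param seed RNG seed; sessions are deterministic given the seed.
#' @return a `session_config` list.
#' @export
session_config <- function(plan = default_plan(),
                           imu_rate = 100, mocap_rate = 120,
                           time_offset = 0.5, imu_jitter_sd = 0,
                           gyro_noise_sd = 0.003, gyro_bias0_sd = 0.005,
                           gyro_bias_walk_sd = 3e-4,
                           accel_noise_sd = 0.004, accel_pulse_g = 0.45,
                           mag_noise_sd = 0.003,
                           hard_iron = c(0.2, -0.1, 0.15),
                           hard_iron_trunk = NULL, hard_iron_chair = NULL,
                           mag_disturb_mag = 0.3, mag_disturb_rate = 0.2,
                           marker_noise_mm = 0.25,
                           occlusion_rate = 0.05, occlusion_gap_mean = 0.12,
                           mounting_deg_trunk = 4, mounting_deg_chair = 8,
                           trunk_amp_deg = 30, push_rate_hz = 1.1,
                           subject_id = "S01", seed = 1) {
  stopifnot(nrow(plan) > 0, all(plan$kind %in% segment_kinds),
            all(plan$duration > 0), imu_rate > 0, mocap_rate > 0,
            time_offset >= 0, imu_jitter_sd >= 0,
            gyro_noise_sd >= 0, gyro_bias0_sd >= 0, gyro_bias_walk_sd >= 0,
            accel_noise_sd >= 0, accel_pulse_g >= 0, mag_noise_sd >= 0,
            mag_disturb_mag >= 0, mag_disturb_rate >= 0,
            marker_noise_mm >= 0, occlusion_rate >= 0,
            occlusion_gap_mean > 0, length(hard_iron) == 3)
  cfg <- as.list(environment())
  if (is.null(cfg$hard_iron_trunk)) cfg$hard_iron_trunk <- hard_iron
  if (is.null(cfg$hard_iron_chair)) cfg$hard_iron_chair <- hard_iron
  structure(cfg, class = "session_config")
}

#' Zero-noise variant of a configuration
#'
#' Sets every noise, disturbance, offset and misalignment parameter to
#' zero, leaving the trajectory plan untouched; the resulting sensor
#' signals are exactly consistent with the ground truth.
#'
#' @param cfg a `session_config`.
#' @param keep_pulses keep the sprint linear-acceleration pulses.
#' @return a `session_config`.
#' @export
zero_noise_config <- function(cfg, keep_pulses = FALSE) {
  cfg$gyro_noise_sd <- 0; cfg$gyro_bias0_sd <- 0; cfg$gyro_bias_walk_sd <- 0
  cfg$accel_noise_sd <- 0; cfg$mag_noise_sd <- 0
  cfg$hard_iron <- c(0, 0, 0)
  cfg$hard_iron_trunk <- c(0, 0, 0); cfg$hard_iron_chair <- c(0, 0, 0)
  cfg$mag_disturb_mag <- 0
  cfg$marker_noise_mm <- 0; cfg$occlusion_rate <- 0
  cfg$mounting_deg_trunk <- 0; cfg$mounting_deg_chair <- 0
  cfg$imu_jitter_sd <- 0
  if (!keep_pulses) cfg$accel_pulse_g <- 0
  cfg
}

smoothstep <- function(u) {
  u <- pmin(1, pmax(0, u))
  3 * u^2 - 2 * u^3
}

quat_about_z <- function(a) cbind(cos(a / 2), 0, 0, sin(a / 2))
quat_about_y <- function(a) cbind(cos(a / 2), 0, sin(a / 2), 0)
quat_about_x <- function(a) cbind(cos(a / 2), sin(a / 2), 0, 0)

random_mounting_quat <- function(max_deg) {
  if (max_deg <= 0) return(c(1, 0, 0, 0))
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0.3, 1) * max_deg * pi / 180
  c(cos(ang / 2), sin(ang / 2) * ax)
}

# Build the keyframed ground-truth channels of one session. Returns spline
# functions of session time for: heading psi, trunk pitch alpha, trunk
# lateral theta, chair wobble pitch, forward pulse p (g), lateral
# acceleration (g), magnetic-disturbance envelope (episodic).
build_channels <- function(cfg) {
  kdt <- 0.1
  plan <- cfg$plan
  t_end <- sum(plan$duration)
  kt <- seq(0, t_end, by = kdt)
  if (kt[length(kt)] < t_end) kt <- c(kt, t_end)
  psi <- alpha <- theta <- wob <- p <- alat <- am <- numeric(length(kt))
  seg_start <- cumsum(c(0, plan$duration))
  psi_base <- 0
  for (s in seq_len(nrow(plan))) {
    t0 <- seg_start[s]; dur <- plan$duration[s]
    in_seg <- kt >= t0 & (kt < t0 + dur | s == nrow(plan))
    u <- (kt[in_seg] - t0) / dur
    tt <- kt[in_seg] - t0
    kind <- plan$kind[s]
    psi_seg <- rep(psi_base, sum(in_seg))
    dynamic <- kind %in% c("sprint", "turn", "collision")
    if (kind == "trunk_rotations") {
      A <- cfg$trunk_amp_deg * pi / 180 * stats::runif(1, 0.9, 1.1)
      f <- 3 / dur
      # flexion-dominant mixing: lateral flexion in phase with flexion, so
      # the helical axis keeps a consistent flexion (y) component and the
      # 1-D signed angle stays coherent between measurement systems
      alpha[in_seg] <- A * sin(2 * pi * f * tt) * smoothstep(u * 6) *
        smoothstep((1 - u) * 6)
      theta[in_seg] <- 0.45 * A * sin(2 * pi * f * tt) *
        smoothstep(u * 6) * smoothstep((1 - u) * 6)
    } else if (kind == "sprint") {
      Ap <- cfg$accel_pulse_g * stats::runif(1, 0.85, 1.15)
      f <- cfg$push_rate_hz * stats::runif(1, 0.9, 1.1)
      env <- smoothstep(u * 4) * smoothstep((1 - u) * 4)
      # push-resolved profile: positive acceleration bursts at push
      # cadence, small rolling deceleration during recovery phases, and a
      # hard braking episode at the end of the sprint
      ph <- sin(2 * pi * f * tt)
      p[in_seg] <- Ap * (1.5 * pmax(0, ph)^2 - 0.18) * env -
        1.1 * Ap * smoothstep((u - 0.82) / 0.05) * smoothstep((0.97 - u) / 0.05)
      # trunk pitches forward with each push (correlated lean)
      alpha[in_seg] <- (12 * pi / 180) * pmax(0, ph)^2 * env
      wob[in_seg] <- (2 * pi / 180) * sin(2 * pi * f * tt + pi / 4) * env
    } else if (kind == "turn") {
      # full turn on the spot: heading returns to its starting value
      dir <- sample(c(-1, 1), 1)
      psi_seg <- psi_base + dir * 2 * pi * smoothstep(u)
      alat[in_seg] <- 0.25 * sin(pi * u)
      alpha[in_seg] <- (5 * pi / 180) * sin(pi * u)
      wob[in_seg] <- (1.5 * pi / 180) * sin(2 * pi * 1.3 * tt) * sin(pi * u)
    } else if (kind == "collision") {
      tm <- dur / 2
      p[in_seg] <- 1.5 * exp(-((tt - tm) / 0.1)^2)
      alpha[in_seg] <- (10 * pi / 180) * exp(-((tt - tm) / 0.25)^2)
    } else if (kind == "ball_handling") {
      alpha[in_seg] <- (40 * pi / 180) * sin(pi * u)^2
      theta[in_seg] <- (8 * pi / 180) * sin(2 * pi * u)
    }
    psi[in_seg] <- psi_seg
    # magnetic-disturbance episodes: bursts at cfg$mag_disturb_rate per
    # second inside dynamic segments, 1-3 s long, clean in between
    if (dynamic && cfg$mag_disturb_mag > 0 && cfg$mag_disturb_rate > 0) {
      n_ep <- stats::rpois(1, cfg$mag_disturb_rate * dur)
      if (kind == "collision") n_ep <- max(n_ep, 1L)
      for (e in seq_len(n_ep)) {
        ec <- stats::runif(1, 0, dur)
        ew <- stats::runif(1, 0.5, 1.5)
        eamp <- cfg$mag_disturb_mag * stats::runif(1, 0.6, 1)
        am[in_seg] <- pmax(am[in_seg], eamp * exp(-((tt - ec) / ew)^2))
      }
    }
  }
  mk <- function(v) stats::splinefun(kt, v, method = "natural")
  list(psi = mk(psi), alpha = mk(alpha), theta = mk(theta), wob = mk(wob),
       pulse = mk(p), alat = mk(alat), am = mk(am),
       t_end = t_end, plan = plan, seg_start = seg_start)
}

segment_kind_at <- function(channels, t) {
  plan <- channels$plan
  idx <- findInterval(t, channels$seg_start, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nrow(plan))
  plan$kind[idx]
}

# Ground-truth segment attitudes at times t (session clock), n x 4 each.
truth_quats <- function(channels, t) {
  psi <- channels$psi(t); alpha <- channels$alpha(t)
  theta <- channels$theta(t); wob <- channels$wob(t)
  qz <- quat_about_z(psi)
  q_chair <- quat_rows_multiply(qz, quat_about_y(wob))
  q_trunk <- quat_rows_multiply(
    quat_rows_multiply(q_chair, quat_about_y(alpha)), quat_about_x(theta))
  list(chair = quat_rows_normalize(q_chair),
       trunk = quat_rows_normalize(q_trunk))
}

# Signed helical inclination of the trunk relative to the chair (degrees),
# closed form from the relative quaternion. The trunk is stacked on the
# chair, so the relative rotation is qy(alpha) (x) qx(theta) regardless of
# heading or chair wobble; neutral pose is alpha = theta = 0.
truth_inclination_deg <- function(channels, t) {
  D <- quat_rows_multiply(quat_about_y(channels$alpha(t)),
                          quat_about_x(channels$theta(t)))
  flip <- D[, 1] < 0
  D[flip, ] <- -D[flip, ]
  vnorm <- sqrt(rowSums(D[, 2:4, drop = FALSE]^2))
  angle <- 2 * atan2(vnorm, D[, 1]) * 180 / pi
  s <- ifelse(vnorm > 1e-12, sign(D[, 3]), 1)
  s[s == 0] <- 1
  angle * s
}

# Gyroscope samples consistent with first-order quaternion integration:
# omega_k is the mean angular rate over (t_{k-1}, t_k], i.e. the rate whose
# one-step Euler update carries q_{k-1} exactly into q_k. This models a
# rate sensor with internal integration; it differs from the instantaneous
# rate by O(dt^2).
gyro_from_quats <- function(Q, dt) {
  n <- nrow(Q)
  dq <- quat_rows_multiply(quat_rows_conjugate(Q[-n, , drop = FALSE]),
                           Q[-1, , drop = FALSE])
  flip <- dq[, 1] < 0
  dq[flip, ] <- -dq[flip, ]
  W <- 2 * dq[, 2:4, drop = FALSE] / (dq[, 1] * dt)
  rbind(W[1, , drop = FALSE], W)
}

#' Generate one synthetic two-sensor session
#'
#' Builds smooth ground-truth trunk and wheelchair trajectories from the
#' segment plan, then synthesizes both IMU streams (gyroscope from the
#' discrete attitude increments, accelerometer from gravity plus the
#' configured linear-acceleration pulses, magnetometer from the rotated
#' earth field plus hard iron and disturbance episodes) and both marker
#' clouds (rigid transforms of fixed cluster geometries plus noise and
#' occlusion gaps). Deterministic given `cfg$seed`.
#'
#' @param cfg a [session_config()].
#' @return a `synthetic_session` list with elements `imu_trunk`,
#'   `imu_chair` (`imu_series`, device clock), `markers_trunk`,
#'   `markers_chair` (`marker_series`, optical clock), `truth` (sensor
#'   attitudes and signed inclination on the IMU grid), `annotations`
#'   (per-IMU-sample segment kind, linear-acceleration and
#'   magnetic-disturbance magnitudes), `subject_id` and `config`.
#' @export
generate_session <- function(cfg) {
  stopifnot(inherits(cfg, "session_config"))
  set.seed(cfg$seed)
  ch <- build_channels(cfg)
  D <- ch$t_end
  qm_trunk <- random_mounting_quat(cfg$mounting_deg_trunk)
  qm_chair <- random_mounting_quat(cfg$mounting_deg_chair)

  # --- IMU grids: device clock starts when the IMU starts recording,
  #     time_offset seconds after the optical system
  n_imu <- floor((D - cfg$time_offset) * cfg$imu_rate) + 1
  t_dev <- (seq_len(n_imu) - 1) / cfg$imu_rate
  if (cfg$imu_jitter_sd > 0) {
    jit <- stats::rnorm(n_imu, 0, cfg$imu_jitter_sd)
    jit[1] <- 0
    t_dev <- sort(t_dev + jit)
    t_dev <- t_dev - t_dev[1]
  }
  t_sess <- t_dev + cfg$time_offset

  tq <- truth_quats(ch, t_sess)
  q_trunk_sensor <- quat_rows_multiply(
    tq$trunk, matrix(qm_trunk, n_imu, 4, byrow = TRUE))
  q_chair_sensor <- quat_rows_multiply(
    tq$chair, matrix(qm_chair, n_imu, 4, byrow = TRUE))

  dt <- diff(t_sess)
  psi <- ch$psi(t_sess)
  pulse <- ch$pulse(t_sess); alat <- ch$alat(t_sess)
  a_lin <- cbind(pulse * cos(psi) - alat * sin(psi),
                 pulse * sin(psi) + alat * cos(psi), 0)
  # the trunk sensor rides on a chest-height lever above the seat: its
  # swing adds trunk-specific linear acceleration (second derivative of
  # the lever position), breaking the correlation between the two sensors'
  # acceleration errors that would otherwise cancel in the relative pose
  lever <- c(0, 0, 0.35); seat <- c(0.1, 0, 0.3)
  pos_rel <- quat_rows_rotate(tq$trunk, matrix(lever, n_imu, 3, byrow = TRUE)) +
    quat_rows_rotate(tq$chair, matrix(seat, n_imu, 3, byrow = TRUE))
  acc_rel <- matrix(0, n_imu, 3)
  for (j in 1:3) {
    acc_rel[, j] <- stats::splinefun(t_sess, pos_rel[, j])(t_sess, deriv = 2)
  }
  a_lin_trunk <- a_lin + acc_rel / 9.81
  up_plus_trunk <- sweep(a_lin_trunk, 2, c(0, 0, 1), "+")
  up_plus_chair <- sweep(a_lin, 2, c(0, 0, 1), "+")

  mag_earth <- c(0.45, 0, -0.75)
  amp_dist <- ch$am(t_sess)
  # wheelchair-fixed disturbance (magnetized frame/wheels active while the
  # chair moves): a persistent, slowly wandering field, much closer to the
  # chair sensor than to the chest-mounted trunk sensor
  dist_field <- function(scale) {
    # dominant dipole axis roughly horizontal (tubular frame geometry)
    u0 <- c(stats::rnorm(2), 0.35 * stats::rnorm(1))
    u0 <- u0 / sqrt(sum(u0^2))
    phases <- stats::runif(3, 0, 2 * pi)
    wander <- cbind(sin(2 * pi * 0.11 * t_sess + phases[1]),
                    sin(2 * pi * 0.07 * t_sess + phases[2]),
                    sin(2 * pi * 0.13 * t_sess + phases[3]))
    scale * amp_dist *
      (matrix(u0, n_imu, 3, byrow = TRUE) + 0.8 * wander) / 1.4
  }
  dist_trunk <- dist_field(0.35)
  dist_chair <- dist_field(1.2)

  make_imu <- function(q_sensor, sensor_id, up_plus, dist_vec, hard_iron) {
    gyro <- gyro_from_quats(q_sensor, dt)
    bias <- matrix(stats::rnorm(3, 0, cfg$gyro_bias0_sd), n_imu, 3, byrow = TRUE) +
      apply(matrix(stats::rnorm(n_imu * 3, 0,
                                cfg$gyro_bias_walk_sd * sqrt(1 / cfg$imu_rate)),
                   n_imu, 3), 2, cumsum)
    gyro <- gyro + bias +
      matrix(stats::rnorm(n_imu * 3, 0, cfg$gyro_noise_sd), n_imu, 3)
    qc <- quat_rows_conjugate(q_sensor)
    accel <- quat_rows_rotate(qc, up_plus) +
      matrix(stats::rnorm(n_imu * 3, 0, cfg$accel_noise_sd), n_imu, 3)
    mag <- quat_rows_rotate(qc, matrix(mag_earth, n_imu, 3, byrow = TRUE)) +
      dist_vec +
      matrix(hard_iron, n_imu, 3, byrow = TRUE) +
      matrix(stats::rnorm(n_imu * 3, 0, cfg$mag_noise_sd), n_imu, 3)
    imu_series(t_dev, gyro, accel, mag, sensor_id = sensor_id,
               nominal_rate = cfg$imu_rate)
  }
  imu_trunk <- make_imu(q_trunk_sensor, "trunk", up_plus_trunk, dist_trunk,
                        cfg$hard_iron_trunk)
  imu_chair <- make_imu(q_chair_sensor, "wheelchair", up_plus_chair, dist_chair,
                        cfg$hard_iron_chair)

  # --- optical markers on the mocap clock
  t_moc <- seq(0, D, by = 1 / cfg$mocap_rate)
  n_moc <- length(t_moc)
  mq <- truth_quats(ch, t_moc)
  pulse_m <- ch$pulse(t_moc)
  psi_m <- ch$psi(t_moc)
  dtm <- 1 / cfg$mocap_rate
  v <- cumsum(pulse_m * 9.81 * dtm)
  pos_chair <- cbind(cumsum(v * cos(psi_m) * dtm),
                     cumsum(v * sin(psi_m) * dtm), 0) * 1000
  pos_trunk <- pos_chair +
    quat_rows_rotate(mq$chair, matrix(c(0, 0, 400), n_moc, 3, byrow = TRUE))

  geom_trunk <- rbind(c(0, 0, 0), c(120, 0, 0), c(0, 100, 0), c(80, 70, 40))
  geom_chair <- rbind(c(0, 0, 0), c(250, 0, 0), c(0, 200, 0),
                      c(200, 150, 50), c(120, 80, -40))
  make_markers <- function(q_seg, pos, geom) {
    k <- nrow(geom)
    P <- matrix(NA_real_, n_moc, 3 * k)
    for (j in seq_len(k)) {
      pj <- pos + quat_rows_rotate(q_seg, matrix(geom[j, ], n_moc, 3, byrow = TRUE))
      if (cfg$marker_noise_mm > 0) {
        pj <- pj + matrix(stats::rnorm(n_moc * 3, 0, cfg$marker_noise_mm), n_moc, 3)
      }
      if (cfg$occlusion_rate > 0) {
        n_gaps <- stats::rpois(1, cfg$occlusion_rate * D)
        if (n_gaps > 0) {
          starts <- stats::runif(n_gaps, 0, D)
          lens <- stats::rexp(n_gaps, 1 / cfg$occlusion_gap_mean)
          for (g in seq_len(n_gaps)) {
            pj[t_moc >= starts[g] & t_moc <= starts[g] + lens[g], ] <- NA_real_
          }
        }
      }
      P[, (3 * j - 2):(3 * j)] <- pj
    }
    marker_series(t_moc, P)
  }
  markers_trunk <- make_markers(mq$trunk, pos_trunk, geom_trunk)
  markers_chair <- make_markers(mq$chair, pos_chair, geom_chair)

  annotations <- data.frame(
    time_s = t_dev,
    kind = segment_kind_at(ch, t_sess),
    accel_mag = sqrt(rowSums(a_lin_trunk^2)),
    mag_disturb = abs(amp_dist)
  )

  structure(list(
    imu_trunk = imu_trunk, imu_chair = imu_chair,
    markers_trunk = markers_trunk, markers_chair = markers_chair,
    truth = list(time_s = t_dev,
                 q_trunk = q_trunk_sensor, q_chair = q_chair_sensor,
                 q_trunk_segment = tq$trunk, q_chair_segment = tq$chair,
                 inclination = inclination_series(
                   t_dev, truth_inclination_deg(ch, t_sess))),
    annotations = annotations,
    subject_id = cfg$subject_id,
    config = cfg
  ), class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> subject %s, %.1f s, %d IMU / %d optical samples\n",
              x$subject_id, max(x$markers_trunk$time_s), nrow(x$imu_trunk),
              nrow(x$markers_trunk)))
  invisible(x)
}

#' Generate a cohort of synthetic subjects
#'
#' Per-subject parameter jitter (trajectory amplitudes 80-125%, noise
#' levels 70-140%, push cadence, inter-system offset 0.2-1.5 s, hard-iron
#' offset, mounting rotations) is drawn from a subject stream derived from
#' the master seed, so cohorts are reproducible and subjects distinct.
#'
#' @param n_subjects number of subjects (`>= 1`).
#' @param base_cfg base [session_config()]; per-subject values jitter
#'   around it.
#' @param seed master seed.
#' @return list of `synthetic_session` objects, one per subject, with ids
#'   `S01`, `S02`, ...
#' @export
generate_cohort <- function(n_subjects, base_cfg = session_config(), seed = 1) {
  stopifnot(n_subjects >= 1)
  lapply(seq_len(n_subjects), function(i) {
    sub_seed <- (seed * 10007L + i * 7919L) %% 2000000000L
    cfg <- base_cfg
    set.seed(sub_seed)
    cfg$trunk_amp_deg <- base_cfg$trunk_amp_deg * stats::runif(1, 0.8, 1.25)
    cfg$accel_pulse_g <- base_cfg$accel_pulse_g * stats::runif(1, 0.8, 1.25)
    cfg$push_rate_hz <- base_cfg$push_rate_hz * stats::runif(1, 0.85, 1.2)
    for (p in c("gyro_noise_sd", "gyro_bias0_sd", "accel_noise_sd",
                "mag_noise_sd", "mag_disturb_mag", "marker_noise_mm")) {
      cfg[[p]] <- base_cfg[[p]] * stats::runif(1, 0.7, 1.4)
    }
    cfg$time_offset <- stats::runif(1, 0.2, 1.5)
    # the trunk IMU is shared equipment (fixed hard iron); each subject
    # brings their own wheelchair (chair-sensor hard iron varies)
    cfg$hard_iron_trunk <- base_cfg$hard_iron
    cfg$hard_iron_chair <- stats::runif(3, -0.3, 0.3)
    cfg$subject_id <- sprintf("S%02d", i)
    cfg$seed <- (sub_seed + 17L) %% 2000000000L
    generate_session(cfg)
  })
}
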