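# Adaptive-gain machinery: trust labels for the earth-frame-only estimate,
# decoding of classifier predictions into a per-sample gain schedule, and
# the grid search for the two gain levels.

#' Adaptive filter configuration
#'
#' @param beta_high gain applied when the earth-frame estimate is trusted.
#' @param beta_low gain applied otherwise; `0 <= beta_low < beta_high <= 1`.
#' @param threshold_deg labelling threshold in degrees (1 degree + the
#'   neutral-pose noise estimate); may be `NA` when labels are not needed.
#' @return an `adaptive_config` list.
#' @export
adaptive_config <- function(beta_high = 0.9635, beta_low = 0.0015,
                            threshold_deg = NA_real_) {
  if (!(beta_low >= 0 && beta_low < beta_high && beta_high <= 1)) {
    stop("need 0 <= beta_low < beta_high <= 1", call. = FALSE)
  }
  structure(list(beta_high = beta_high, beta_low = beta_low,
                 threshold_deg = threshold_deg), class = "adaptive_config")
}

angle_vector <- function(x) {
  if (inherits(x, "inclination_series")) x$angle_deg else as.numeric(x)
}

#' Neutral-pose noise estimate for the labelling threshold
#'
#' Standard deviation of the difference between the earth-frame-only and
#' the reference inclination over the static neutral window at the start of
#' the session. Offsets do not contribute (it is a standard deviation, not
#' an RMS). The labelling threshold is `1 + noise` degrees.
#'
#' @param ef_angle,ref_angle `inclination_series` (or numeric vectors with
#'   `time_s` supplied) covering the neutral window.
#' @param neutral_window window length from the series start, seconds.
#' @param time_s timestamps, required when the inputs are bare vectors.
#' @return noise standard deviation in degrees.
#' @export
estimate_noise <- function(ef_angle, ref_angle, neutral_window = 20,
                           time_s = NULL) {
  if (is.null(time_s)) {
    if (!inherits(ef_angle, "inclination_series")) {
      stop("supply time_s or inclination_series inputs", call. = FALSE)
    }
    time_s <- ef_angle$time_s
  }
  ef <- angle_vector(ef_angle); ref <- angle_vector(ref_angle)
  stopifnot(length(ef) == length(ref), length(ef) == length(time_s))
  win <- time_s - time_s[1] < neutral_window
  if ((time_s[length(time_s)] - time_s[1]) < neutral_window) {
    stop("series shorter than the neutral window", call. = FALSE)
  }
  stats::sd(ef[win] - ref[win], na.rm = TRUE)
}

#' Mean neutral-pose noise over several subjects
#'
#' @param pairs list of `list(ef, ref)` pairs (see [estimate_noise()]).
#' @param neutral_window window length in seconds.
#' @return mean of the per-subject noise estimates, degrees.
#' @export
estimate_noise_mean <- function(pairs, neutral_window = 20) {
  mean(vapply(pairs, function(p) {
    estimate_noise(p$ef, p$ref, neutral_window = neutral_window)
  }, numeric(1)))
}

#' Trust labels for the earth-frame-only estimate
#'
#' A sample is labelled correct (1) in `efcorrect` when the absolute
#' difference between the earth-frame-only and the reference inclination is
#' strictly below `threshold_deg`. The stricter `efcorrect_s5` labels a
#' sample 1 only when all five consecutive samples centred on it (the
#' sample, two preceding and two following; truncated at the series ends)
#' are below the threshold, guarding against coincidental intersections of
#' a deviating estimate with the reference. Missing differences count as
#' incorrect.
#'
#' @param ef_angle,ref_angle aligned `inclination_series` or numeric vectors.
#' @param threshold_deg threshold in degrees (1 + noise).
#' @param time_s timestamps when the inputs are bare vectors.
#' @return a `label_series`.
#' @export
make_labels <- function(ef_angle, ref_angle, threshold_deg, time_s = NULL) {
  if (is.null(time_s)) {
    time_s <- if (inherits(ef_angle, "inclination_series")) {
      ef_angle$time_s
    } else {
      seq_along(angle_vector(ef_angle))
    }
  }
  ef <- angle_vector(ef_angle); ref <- angle_vector(ref_angle)
  if (length(ef) != length(ref)) {
    stop("series must be aligned and equally long", call. = FALSE)
  }
  stopifnot(is.numeric(threshold_deg), threshold_deg > 0)
  d <- abs(ef - ref)
  ok <- !is.na(d) & d < threshold_deg
  n <- length(ok)
  s5 <- ok
  for (off in c(-2L, -1L, 1L, 2L)) {
    idx <- seq_len(n) + off
    inside <- idx >= 1L & idx <= n
    s5[inside] <- s5[inside] & ok[idx[inside]]
  }
  label_series(time_s, as.integer(ok), as.integer(s5))
}

#' Decode binary trust predictions into a gain schedule
#'
#' @param predictions binary (0/1) vector; 1 = earth-frame estimate trusted.
#' @param cfg an [adaptive_config()].
#' @return numeric vector: `beta_high` where 1, `beta_low` where 0.
#' @export
decode_beta <- function(predictions, cfg = adaptive_config()) {
  predictions <- as.numeric(predictions)
  if (anyNA(predictions) || !all(predictions %in% c(0, 1))) {
    stop("predictions must be binary 0/1", call. = FALSE)
  }
  ifelse(predictions == 1, cfg$beta_high, cfg$beta_low)
}

session_rmse <- function(session, beta_schedule) {
  est_t <- run_filter(session$imu_trunk, beta_schedule)
  est_c <- run_filter(session$imu_chair, beta_schedule)
  incl <- inclination(est_t, est_c, neutral_index = session$neutral_index)
  d <- incl$angle_deg - angle_vector(session$ref)
  sqrt(mean(d^2, na.rm = TRUE))
}

# Precomputed arrays for the grid-search hot loop: one filter run per
# sensor per gain pair without container overhead.
session_fastdata <- function(session) {
  mk <- function(imu) {
    accel <- imu_matrix(imu, "accel"); mag <- imu_matrix(imu, "mag")
    list(gyro = imu_matrix(imu, "gyro"), accel = accel, mag = mag,
         dt = c(0, diff(imu$time_s)),
         q0 = earth_frame_only(accel[1, ], mag[1, ]))
  }
  list(trunk = mk(session$imu_trunk), chair = mk(session$imu_chair),
       ref = angle_vector(session$ref),
       neutral = session$neutral_index)
}

session_rmse_fast <- function(fd, beta_schedule) {
  qt <- mw_filter_cpp(fd$trunk$gyro, fd$trunk$accel, fd$trunk$mag,
                      beta_schedule, fd$trunk$dt, fd$trunk$q0)$q
  qc <- mw_filter_cpp(fd$chair$gyro, fd$chair$accel, fd$chair$mag,
                      beta_schedule, fd$chair$dt, fd$chair$q0)$q
  qrel <- quat_rows_multiply(quat_rows_conjugate(qc), qt)
  q0 <- qrel[fd$neutral, ]
  n <- nrow(qrel)
  D <- quat_rows_multiply(matrix(quat_conjugate(q0), n, 4, byrow = TRUE), qrel)
  flip <- D[, 1] < 0
  D[flip, ] <- -D[flip, ]
  vnorm <- sqrt(D[, 2]^2 + D[, 3]^2 + D[, 4]^2)
  theta <- 2 * atan2(vnorm, D[, 1]) * 180 / pi
  y_ref <- as.numeric(quat_rows_rotate(
    matrix(quat_conjugate(q0), 1, 4), matrix(c(0, 1, 0), 1, 3)))
  proj <- D[, 2] * y_ref[1] + D[, 3] * y_ref[2] + D[, 4] * y_ref[3]
  s <- ifelse(vnorm > 1e-12, sign(proj), 1)
  s[s == 0] <- 1
  d <- theta * s - fd$ref
  sqrt(mean(d^2, na.rm = TRUE))
}

#' Grid search for the two correction-gain levels
#'
#' For every combination of `beta_low` (default 0 to 0.01 in steps of
#' 0.001) and `beta_high` (default 0.5 to 1 in steps of 0.025), decodes the
#' oracle labels of each session into a gain schedule, runs the adaptive
#' filter on both sensors, and records the mean inclination RMSE against
#' the reference across sessions. Because near-minimal RMSE typically forms
#' a plateau, the returned gains are the means of the `beta_low` and
#' `beta_high` values participating in combinations whose RMSE is within
#' `plateau_tol` (relative) of the minimum.
#'
#' @param sessions list of prepared sessions, each a list with
#'   `imu_trunk`, `imu_chair` (`imu_series` on the common grid), `labels`
#'   (`label_series` or binary vector), `ref` (reference
#'   `inclination_series` aligned to the IMU grid) and `neutral_index`.
#' @param beta_low_grid,beta_high_grid candidate gain grids.
#' @param label_variant which label column to use when `labels` is a
#'   `label_series`.
#' @param plateau_tol relative RMSE tolerance defining the plateau.
#' @return list with `beta_low`, `beta_high` (plateau means), `argmin`
#'   (single best pair), `surface` (RMSE matrix, rows `beta_low`), and
#'   `plateau` (logical matrix).
#' @export
grid_search_beta <- function(sessions,
                             beta_low_grid = seq(0, 0.01, by = 0.001),
                             beta_high_grid = seq(0.5, 1, by = 0.025),
                             label_variant = c("efcorrect", "efcorrect_s5"),
                             plateau_tol = 0.01) {
  if (!length(sessions)) stop("empty session list", call. = FALSE)
  label_variant <- match.arg(label_variant)
  labels <- lapply(sessions, function(s) {
    l <- s$labels
    if (inherits(l, "label_series")) l[[label_variant]] else as.numeric(l)
  })
  fast <- lapply(sessions, session_fastdata)
  surface <- matrix(NA_real_, length(beta_low_grid), length(beta_high_grid),
                    dimnames = list(beta_low_grid, beta_high_grid))
  for (i in seq_along(beta_low_grid)) {
    for (j in seq_along(beta_high_grid)) {
      cfg <- adaptive_config(beta_high = beta_high_grid[j],
                             beta_low = beta_low_grid[i])
      rmse <- vapply(seq_along(sessions), function(k) {
        session_rmse_fast(fast[[k]], decode_beta(labels[[k]], cfg))
      }, numeric(1))
      surface[i, j] <- mean(rmse)
    }
  }
  best <- min(surface)
  plateau <- surface <= best * (1 + plateau_tol)
  amin <- which(surface == best, arr.ind = TRUE)[1, ]
  list(
    beta_low = mean(beta_low_grid[unique(which(plateau, arr.ind = TRUE)[, 1])]),
    beta_high = mean(beta_high_grid[unique(which(plateau, arr.ind = TRUE)[, 2])]),
    argmin = c(beta_low = beta_low_grid[amin[1]],
               beta_high = beta_high_grid[amin[2]]),
    surface = surface,
    plateau = plateau
  )
}

#' Run the adaptive (classifier-gated) filter on a two-sensor session
#'
#' Builds the 18 raw-signal features from the two sensors, obtains
#' per-sample trust predictions from the model, decodes them into a gain
#' schedule ([decode_beta()]) and runs the filter on both sensors with that
#' schedule. The prediction at sample t gates the update producing the
#' attitude at t (no lookahead), so the scheme is causal and
#' streaming-capable.
#'
#' @param imu_trunk,imu_chair `imu_series` on a common uniform grid.
#' @param model a trained trust model (see [train_trust_classifier()]), or
#'   a function mapping the feature data.frame to a binary vector (useful
#'   for oracle-label or constant stubs).
#' @param cfg an [adaptive_config()].
#' @return list with `trunk`, `chair` (`orientation_series` carrying the
#'   per-sample gain provenance), `beta` (the schedule) and `predictions`.
#' @export
run_extended <- function(imu_trunk, imu_chair, model,
                         cfg = adaptive_config()) {
  stopifnot(inherits(imu_trunk, "imu_series"), inherits(imu_chair, "imu_series"))
  if (nrow(imu_trunk) != nrow(imu_chair)) {
    stop("sensor streams must be equally long", call. = FALSE)
  }
  feats <- session_features(imu_trunk, imu_chair)
  pred <- if (is.function(model)) model(feats) else predict_trust(model, feats)
  pred <- as.numeric(pred)
  if (length(pred) != nrow(feats) || !all(pred %in% c(0, 1))) {
    stop("model must return one binary prediction per sample", call. = FALSE)
  }
  beta <- decode_beta(pred, cfg)
  list(trunk = run_filter(imu_trunk, beta),
       chair = run_filter(imu_chair, beta),
       beta = beta,
       predictions = pred)
}
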