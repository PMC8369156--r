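# Pre-processing of raw IMU and optical-marker series: hard-iron offset
# correction, spline resampling to a common rate, short-gap interpolation,
# marker-cluster orientation frames and cross-correlation time alignment.

#' Hard-iron magnetometer offset correction
#'
#' Fits a sphere to the magnetometer cloud by linear least squares (the
#' algebraic sphere fit: `|m|^2 = 2 c . m + (r^2 - |c|^2)`) and subtracts
#' the fitted centre, removing the constant bias caused by magnetized
#' material moving with the sensor. The soft-iron (ellipsoidal) distortion
#' is deliberately not modelled.
#'
#' If the directional coverage is degenerate (rank-deficient normal
#' equations), the fit falls back to the per-axis midpoint
#' `(min + max) / 2` and flags the result.
#'
#' @param mag n x 3 numeric matrix of raw magnetometer samples.
#' @return list with `corrected` (n x 3 matrix), `offset` (numeric(3)) and
#'   `fallback` (logical, `TRUE` when the midpoint fallback was used).
#' @export
correct_hard_iron <- function(mag) {
  mag <- as.matrix(mag)
  stopifnot(ncol(mag) == 3)
  ok <- stats::complete.cases(mag)
  M <- mag[ok, , drop = FALSE]
  if (nrow(M) < 4) stop("need at least 4 magnetometer samples", call. = FALSE)
  A <- cbind(2 * M, 1)
  y <- rowSums(M^2)
  qrA <- qr(A)
  fallback <- FALSE
  if (qrA$rank < 4L) {
    fallback <- TRUE
  } else {
    # also treat near-singular systems (e.g. coplanar coverage) as degenerate
    d <- abs(diag(qr.R(qrA)))
    if (min(d) / max(d) < 1e-10) fallback <- TRUE
  }
  if (fallback) {
    warning("degenerate magnetometer coverage; using per-axis midpoint offset",
            call. = FALSE)
    offset <- (apply(M, 2, min) + apply(M, 2, max)) / 2
  } else {
    offset <- as.numeric(qr.coef(qrA, y)[1:3])
    # robust re-fit: samples recorded during magnetic-disturbance episodes
    # do not lie on the hard-iron sphere; trim radius outliers and refit
    keep_pts <- rep(TRUE, nrow(M))
    for (it in 1:3) {
      Dv <- sweep(M, 2, offset)
      dist <- sqrt(rowSums(Dv^2))
      dev <- abs(dist - stats::median(dist[keep_pts]))
      cut <- 3.5 * stats::mad(dist[keep_pts])
      if (!is.finite(cut) || cut <= 0) break
      keep_pts <- dev < cut
      if (sum(keep_pts) < 0.2 * nrow(M)) break
      Ak <- cbind(2 * M[keep_pts, , drop = FALSE], 1)
      yk <- rowSums(M[keep_pts, , drop = FALSE]^2)
      offset <- as.numeric(qr.coef(qr(Ak), yk)[1:3])
    }
    M <- M[keep_pts, , drop = FALSE]
    # Gauss-Newton refinement of the geometric sphere fit: the algebraic
    # (Kasa) seed is biased when the directional coverage is partial
    for (it in 1:25) {
      Dv <- sweep(M, 2, offset)
      dist <- sqrt(rowSums(Dv^2))
      r <- mean(dist)
      U <- Dv / dist                      # d(dist)/d(offset) = -u
      res <- dist - r
      Uc <- sweep(U, 2, colMeans(U))      # account for r = mean(dist)
      JtJ <- crossprod(Uc)
      g <- crossprod(Uc, res)
      # update only well-excited directions: with quasi-planar coverage
      # (e.g. heading-only rotation) the center is unobservable along the
      # plane normal and the step must not extrapolate there
      eg <- eigen(JtJ, symmetric = TRUE)
      keep <- eg$values > 1e-3 * eg$values[1]
      if (!any(keep)) break
      inv <- eg$vectors[, keep, drop = FALSE] %*%
        (t(eg$vectors[, keep, drop = FALSE]) / eg$values[keep])
      step <- inv %*% g
      offset <- offset + as.numeric(step)
      if (sqrt(sum(step^2)) < 1e-10 * max(r, 1)) break
    }
  }
  offset <- as.numeric(offset)
  list(corrected = sweep(mag, 2, offset), offset = offset, fallback = fallback)
}

#' Zero the gyroscope bias on the initial static window
#'
#' Sessions start with a static neutral pose; the mean angular rate over
#' the initial window estimates the constant gyroscope bias, which is
#' subtracted from the whole series (startup bias calibration). In-run
#' bias instability is not removable this way and remains.
#'
#' @param imu an `imu_series` whose recording starts at rest.
#' @param window_s length of the startup window, seconds.
#' @return list with `imu` (corrected series) and `bias` (numeric(3), rad/s).
#' @export
correct_gyro_bias <- function(imu, window_s = 10) {
  stopifnot(inherits(imu, "imu_series"), window_s > 0)
  win <- imu$time_s - imu$time_s[1] < window_s
  if (sum(win) < 10) stop("startup window too short", call. = FALSE)
  gyro <- imu_matrix(imu, "gyro")
  bias <- colMeans(gyro[win, , drop = FALSE])
  out <- imu_series(imu$time_s, sweep(gyro, 2, bias),
                    imu_matrix(imu, "accel"), imu_matrix(imu, "mag"),
                    sensor_id = attr(imu, "sensor_id"),
                    nominal_rate = attr(imu, "nominal_rate"))
  list(imu = out, bias = as.numeric(bias))
}

uniform_grid <- function(t0, t1, rate) {
  # uniform grid at `rate` Hz spanning [t0, t1] without extrapolation
  t0 + seq(0, floor((t1 - t0) * rate + 1e-9)) / rate
}

#' Resample a series onto a uniform grid by cubic splines
#'
#' Each channel is interpolated with a cubic spline (`stats::splinefun`,
#' `method = "fmm"`) onto a uniform grid at `target_rate` spanning the
#' original time support; no extrapolation is performed.
#'
#' For marker series, samples on the new grid are kept only where the
#' original series has observed neighbours on both sides within 1.5 median
#' sample intervals; resampled samples falling inside remaining gaps stay
#' missing.
#'
#' @param x an `imu_series`, `marker_series`, or data.frame with a `time_s`
#'   column.
#' @param target_rate target rate in Hz (default 100).
#' @return object of the same class on the uniform grid.
#' @export
resample_to <- function(x, target_rate = 100) UseMethod("resample_to")

resample_channels <- function(time_s, X, grid) {
  out <- matrix(NA_real_, length(grid), ncol(X))
  for (j in seq_len(ncol(X))) {
    out[, j] <- stats::splinefun(time_s, X[, j], method = "fmm")(grid)
  }
  colnames(out) <- colnames(X)
  out
}

#' @export
resample_to.imu_series <- function(x, target_rate = 100) {
  if (nrow(x) < 4) stop("need at least 4 samples to resample", call. = FALSE)
  grid <- uniform_grid(x$time_s[1], x$time_s[nrow(x)], target_rate)
  X <- resample_channels(x$time_s, as.matrix(x[, imu_channel_names]), grid)
  imu_series(grid, X[, 1:3], X[, 4:6], X[, 7:9],
             sensor_id = attr(x, "sensor_id"), nominal_rate = target_rate)
}

#' @export
resample_to.marker_series <- function(x, target_rate = 100) {
  if (nrow(x) < 4) stop("need at least 4 samples to resample", call. = FALSE)
  time_s <- x$time_s
  grid <- uniform_grid(time_s[1], time_s[nrow(x)], target_rate)
  X <- as.matrix(x[, -1, drop = FALSE])
  dt_med <- stats::median(diff(time_s))
  out <- matrix(NA_real_, length(grid), ncol(X))
  for (j in seq_len(ncol(X))) {
    obs <- which(!is.na(X[, j]))
    if (length(obs) < 4) next
    to <- time_s[obs]
    f <- stats::splinefun(to, X[obs, j], method = "fmm")
    # valid only with an observed neighbour on each side, close enough
    lo <- findInterval(grid, to)
    valid <- lo >= 1 & lo < length(to)
    valid[valid] <- (grid[valid] - to[lo[valid]]) <= 1.5 * dt_med &
      (to[lo[valid] + 1] - grid[valid]) <= 1.5 * dt_med
    valid[grid %in% to] <- TRUE
    out[valid, j] <- f(grid[valid])
  }
  colnames(out) <- colnames(X)
  marker_series(grid, out)
}

#' @export
resample_to.data.frame <- function(x, target_rate = 100) {
  if (nrow(x) < 4) stop("need at least 4 samples to resample", call. = FALSE)
  if (any(diff(x$time_s) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  grid <- uniform_grid(x$time_s[1], x$time_s[nrow(x)], target_rate)
  X <- resample_channels(x$time_s, as.matrix(x[, -1, drop = FALSE]), grid)
  out <- data.frame(time_s = grid, X)
  names(out) <- names(x)
  out
}

#' Interpolate short occlusion gaps in a marker series
#'
#' Gaps strictly shorter than `max_gap` seconds (measured as the number of
#' missing samples times the median sample interval) are filled by per-axis
#' cubic splines over the observed samples. Longer gaps, and gaps touching
#' the series boundary, are left missing; no extrapolation ever happens.
#'
#' @param x a `marker_series`.
#' @param max_gap maximum gap duration to fill, seconds (default 0.2).
#' @return a `marker_series` with short gaps filled.
#' @export
interpolate_gaps <- function(x, max_gap = 0.2) {
  stopifnot(inherits(x, "marker_series"))
  time_s <- x$time_s
  dt_med <- stats::median(diff(time_s))
  X <- as.matrix(x[, -1, drop = FALSE])
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (!any(miss) || all(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    obs <- which(!miss)
    if (length(obs) < 4) next
    f <- stats::splinefun(time_s[obs], X[obs, j], method = "fmm")
    for (i in which(r$values)) {
      if (starts[i] == 1 || ends[i] == nrow(X)) next  # boundary: never fill
      if (r$lengths[i] * dt_med < max_gap) {
        idx <- starts[i]:ends[i]
        X[idx, j] <- f(time_s[idx])
      }
    }
  }
  marker_series(time_s, X)
}

#' Build marker-cluster orientation frames
#'
#' Selects the three markers with the fewest missing samples (ties broken
#' toward the lower marker index) and constructs, per sample, the
#' right-handed triad `x = unit(m2 - m1)`, `z = unit(x %x% (m3 - m1))`,
#' `y = z %x% x`, assembled column-wise into the cluster attitude
#' (`v_global = R %*% v_local`). Samples with any selected marker missing,
#' or with (near-)collinear markers, are flagged invalid.
#'
#' The triad construction itself is arbitrary; downstream inclination is
#' referenced to a neutral pose, which cancels the arbitrary cluster
#' placement.
#'
#' @param x a `marker_series` with at least 3 markers.
#' @return a `frame_series`.
#' @export
build_cluster_frames <- function(x) {
  stopifnot(inherits(x, "marker_series"))
  k <- attr(x, "n_markers")
  if (k < 3) stop("need at least 3 markers", call. = FALSE)
  n_missing <- vapply(seq_len(k), function(i) {
    sum(!stats::complete.cases(marker_positions(x, i)))
  }, integer(1))
  sel <- order(n_missing)[1:3]
  m1 <- marker_positions(x, sel[1])
  m2 <- marker_positions(x, sel[2])
  m3 <- marker_positions(x, sel[3])
  n <- nrow(x)
  R <- array(NA_real_, c(3, 3, n))
  valid <- rep(FALSE, n)
  u <- m2 - m1
  w <- m3 - m1
  un <- sqrt(rowSums(u^2))
  for (i in seq_len(n)) {
    if (anyNA(u[i, ]) || anyNA(w[i, ]) || un[i] < 1e-9) next
    xv <- u[i, ] / un[i]
    zv <- c(xv[2] * w[i, 3] - xv[3] * w[i, 2],
            xv[3] * w[i, 1] - xv[1] * w[i, 3],
            xv[1] * w[i, 2] - xv[2] * w[i, 1])
    zn <- sqrt(sum(zv^2))
    if (zn < 1e-6 * sqrt(sum(w[i, ]^2))) next  # collinear markers
    zv <- zv / zn
    yv <- c(zv[2] * xv[3] - zv[3] * xv[2],
            zv[3] * xv[1] - zv[1] * xv[3],
            zv[1] * xv[2] - zv[2] * xv[1])
    R[, , i] <- cbind(xv, yv, zv)
    valid[i] <- TRUE
  }
  frame_series(x$time_s, R, valid)
}

#' Time lag between two angle series by cross-correlation
#'
#' Both series are z-scored and the integer lag maximizing their
#' cross-correlation within `± max_lag_s` is returned. A positive returned
#' lag means series `b` starts later (is delayed) relative to `a` by that
#' many samples: shifting `b` earlier by `lag` samples aligns the two.
#' Exact ties are broken toward the smallest `|lag|`, and between equal
#' magnitudes toward the negative lag.
#'
#' @param a,b numeric series sampled at the same `rate`.
#' @param rate common sample rate, Hz.
#' @param max_lag_s search window in seconds (default 10).
#' @return integer lag in samples.
#' @export
sync_by_xcorr <- function(a, b, rate = 100, max_lag_s = 10) {
  xcorr_best(a, b, rate = rate, max_lag_s = max_lag_s)$lag
}

# Full cross-correlation result: best lag and the correlation there.
# Used by sync_by_xcorr and by the preparation step (which additionally
# resolves the arbitrary sign of optical cluster axes by comparing the
# correlation of b and -b).
xcorr_best <- function(a, b, rate = 100, max_lag_s = 10) {
  a <- as.numeric(a); b <- as.numeric(b)
  a[is.na(a)] <- mean(a, na.rm = TRUE)
  b[is.na(b)] <- mean(b, na.rm = TRUE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant series: cross-correlation undefined", call. = FALSE)
  }
  if (min(length(a), length(b)) / rate < 10) {
    stop("need at least 10 s of overlap", call. = FALSE)
  }
  az <- (a - mean(a)) / stats::sd(a)
  bz <- (b - mean(b)) / stats::sd(b)
  max_lag <- min(round(max_lag_s * rate), length(a) - 2L, length(b) - 2L)
  cc <- stats::ccf(az, bz, lag.max = max_lag, plot = FALSE,
                   na.action = stats::na.pass)
  # ccf lag k correlates a[t+k] with b[t]; b delayed by L peaks at k = -L
  lags <- -as.numeric(cc$lag)
  val <- as.numeric(cc$acf)
  best <- max(val)
  cand <- lags[val >= best - 1e-12]
  cand <- cand[order(abs(cand), cand)]  # smallest |lag|, then negative first
  list(lag = as.integer(cand[1]), value = best)
}
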