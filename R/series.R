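# Time-series containers. All are thin S3 classes over data.frames (or a
# list with a rotation-matrix array) so that users can fall back to plain
# data-frame tooling at any point.

imu_channel_names <- c(
  "gyro_x", "gyro_y", "gyro_z",
  "accel_x", "accel_y", "accel_z",
  "mag_x", "mag_y", "mag_z"
)

#' IMU time series
#'
#' Time-stamped 9-axis samples of one sensor: 3D gyroscope (rad/s), 3D
#' accelerometer (g units) and 3D magnetometer (arbitrary field units).
#'
#' @param time_s numeric, strictly increasing timestamps in seconds.
#' @param gyro,accel,mag n x 3 numeric matrices.
#' @param sensor_id `"trunk"` or `"wheelchair"`.
#' @param nominal_rate nominal sample rate in Hz.
#' @return an `imu_series`, a data.frame with columns `time_s`, `gyro_*`,
#'   `accel_*`, `mag_*` and attributes `sensor_id`, `nominal_rate`.
#' @export
imu_series <- function(time_s, gyro, accel, mag,
                       sensor_id = c("trunk", "wheelchair"),
                       nominal_rate = 100) {
  sensor_id <- match.arg(sensor_id)
  gyro <- as.matrix(gyro); accel <- as.matrix(accel); mag <- as.matrix(mag)
  n <- length(time_s)
  stopifnot(nrow(gyro) == n, nrow(accel) == n, nrow(mag) == n,
            ncol(gyro) == 3, ncol(accel) == 3, ncol(mag) == 3)
  if (n > 1 && any(diff(time_s) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  df <- data.frame(time_s = time_s, gyro, accel, mag)
  names(df) <- c("time_s", imu_channel_names)
  structure(df, class = c("imu_series", "data.frame"),
            sensor_id = sensor_id, nominal_rate = nominal_rate)
}

#' @export
print.imu_series <- function(x, ...) {
  cat(sprintf("<imu_series> sensor '%s', %d samples, %.6g-%.6g s, nominal %g Hz\n",
              attr(x, "sensor_id"), nrow(x), min(x$time_s), max(x$time_s),
              attr(x, "nominal_rate")))
  invisible(x)
}

#' Extract one 3-axis channel matrix from an IMU series
#' @param x an `imu_series`.
#' @param which channel: `"gyro"`, `"accel"` or `"mag"`.
#' @return n x 3 numeric matrix.
#' @export
imu_matrix <- function(x, which = c("gyro", "accel", "mag")) {
  which <- match.arg(which)
  as.matrix(x[, paste0(which, "_", c("x", "y", "z"))])
}

#' Read / write an IMU series CSV
#'
#' Columns: `time_s, gyro_x, gyro_y, gyro_z, accel_x, accel_y, accel_z,
#' mag_x, mag_y, mag_z`, with a header row.
#'
#' @param path file path.
#' @param sensor_id,nominal_rate passed to [imu_series()].
#' @return [read_imu_csv()] returns an `imu_series`; [write_imu_csv()]
#'   returns `path` invisibly.
#' @export
read_imu_csv <- function(path, sensor_id = "trunk", nominal_rate = 100) {
  df <- utils::read.csv(path)
  need <- c("time_s", imu_channel_names)
  if (!all(need %in% names(df))) {
    stop("IMU CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  imu_series(df$time_s,
             as.matrix(df[, c("gyro_x", "gyro_y", "gyro_z")]),
             as.matrix(df[, c("accel_x", "accel_y", "accel_z")]),
             as.matrix(df[, c("mag_x", "mag_y", "mag_z")]),
             sensor_id = sensor_id, nominal_rate = nominal_rate)
}

#' @rdname read_imu_csv
#' @param x an `imu_series`.
#' @export
write_imu_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Optical marker time series
#'
#' Time-stamped 3D marker positions in mm; `NA` marks missing (occluded)
#' samples.
#'
#' @param time_s numeric timestamps, strictly increasing.
#' @param positions n x (3k) numeric matrix, columns `marker{k}_{x,y,z}`.
#' @return a `marker_series` data.frame.
#' @export
marker_series <- function(time_s, positions) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == length(time_s), ncol(positions) %% 3 == 0)
  if (length(time_s) > 1 && any(diff(time_s) <= 0)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  k <- ncol(positions) / 3
  if (is.null(colnames(positions))) {
    colnames(positions) <- paste0("marker", rep(seq_len(k), each = 3), "_",
                                  rep(c("x", "y", "z"), k))
  }
  rownames(positions) <- NULL
  df <- data.frame(time_s = time_s, positions, check.names = FALSE)
  rownames(df) <- NULL
  structure(df, class = c("marker_series", "data.frame"), n_markers = k)
}

#' @export
print.marker_series <- function(x, ...) {
  miss <- mean(is.na(as.matrix(x[, -1]))) * 100
  cat(sprintf("<marker_series> %d markers, %d samples, %.1f%% missing\n",
              attr(x, "n_markers"), nrow(x), miss))
  invisible(x)
}

marker_positions <- function(x, k) {
  as.matrix(x[, paste0("marker", k, "_", c("x", "y", "z"))])
}

#' Read / write a marker series CSV
#'
#' Columns `time_s` then `marker{k}_{x,y,z}` in mm; empty cells denote
#' missing samples.
#'
#' @param path file path.
#' @return [read_marker_csv()] returns a `marker_series`.
#' @export
read_marker_csv <- function(path) {
  df <- utils::read.csv(path)
  if (names(df)[1] != "time_s") stop("first column must be time_s", call. = FALSE)
  marker_series(df$time_s, as.matrix(df[, -1, drop = FALSE]))
}

#' @rdname read_marker_csv
#' @param x a `marker_series`.
#' @export
write_marker_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Rotation-matrix (cluster frame) time series
#'
#' @param time_s timestamps in seconds.
#' @param R 3 x 3 x n array of rotation matrices (cluster axes expressed in
#'   the global frame: `v_global = R %*% v_local`).
#' @param valid logical vector flagging samples whose frame is usable.
#' @return a `frame_series` list.
#' @export
frame_series <- function(time_s, R, valid = rep(TRUE, length(time_s))) {
  stopifnot(length(dim(R)) == 3, dim(R)[1] == 3, dim(R)[2] == 3,
            dim(R)[3] == length(time_s), length(valid) == length(time_s))
  structure(list(time_s = time_s, R = R, valid = valid),
            class = "frame_series")
}

#' @export
print.frame_series <- function(x, ...) {
  cat(sprintf("<frame_series> %d samples, %d valid\n",
              length(x$time_s), sum(x$valid)))
  invisible(x)
}

#' Orientation time series
#'
#' Per-sample attitude quaternions together with the correction gain (beta)
#' actually applied at each update, recording the gain schedule provenance
#' of adaptive runs.
#'
#' @param time_s timestamps in seconds.
#' @param q n x 4 matrix of unit quaternions (w, x, y, z).
#' @param beta numeric vector of per-sample correction gains.
#' @param degenerate logical; samples where accel/mag were unusable and a
#'   gyro-only step was taken.
#' @return an `orientation_series` data.frame with columns `time_s, qw, qx,
#'   qy, qz, beta`.
#' @export
orientation_series <- function(time_s, q, beta,
                               degenerate = rep(FALSE, length(time_s))) {
  q <- as.matrix(q)
  stopifnot(nrow(q) == length(time_s), ncol(q) == 4,
            length(beta) %in% c(1L, length(time_s)))
  if (length(beta) == 1L) beta <- rep(beta, length(time_s))
  df <- data.frame(time_s = time_s, qw = q[, 1], qx = q[, 2], qy = q[, 3],
                   qz = q[, 4], beta = beta)
  structure(df, class = c("orientation_series", "data.frame"),
            degenerate = degenerate)
}

#' @export
print.orientation_series <- function(x, ...) {
  cat(sprintf("<orientation_series> %d samples, beta in [%g, %g]\n",
              nrow(x), min(x$beta), max(x$beta)))
  invisible(x)
}

#' Extract the n x 4 quaternion matrix of an orientation series
#' @param x an `orientation_series`.
#' @return n x 4 numeric matrix (w, x, y, z).
#' @export
orientation_quats <- function(x) as.matrix(x[, c("qw", "qx", "qy", "qz")])

#' @rdname orientation_series
#' @param x an `orientation_series`.
#' @param path file path.
#' @export
write_orientation_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Signed trunk-inclination time series
#'
#' One-dimensional helical inclination angle in degrees between a distal
#' (trunk) and proximal (wheelchair) segment, zero at the neutral-pose
#' reference sample, flexion positive.
#'
#' @param time_s timestamps in seconds.
#' @param angle_deg signed angles in degrees (`NA` where frames were invalid).
#' @return an `inclination_series` data.frame with columns `time_s, angle_deg`.
#' @export
inclination_series <- function(time_s, angle_deg) {
  stopifnot(length(time_s) == length(angle_deg))
  ok <- angle_deg[!is.na(angle_deg)]
  if (length(ok) && max(abs(ok)) > 180 + 1e-9) {
    stop("|angle_deg| must be <= 180", call. = FALSE)
  }
  structure(data.frame(time_s = time_s, angle_deg = angle_deg),
            class = c("inclination_series", "data.frame"))
}

#' @export
print.inclination_series <- function(x, ...) {
  cat(sprintf("<inclination_series> %d samples, range [%.2f, %.2f] deg\n",
              nrow(x), min(x$angle_deg, na.rm = TRUE),
              max(x$angle_deg, na.rm = TRUE)))
  invisible(x)
}

#' @rdname inclination_series
#' @param x an `inclination_series`.
#' @param path file path.
#' @export
write_inclination_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname inclination_series
#' @export
read_inclination_csv <- function(path) {
  df <- utils::read.csv(path)
  inclination_series(df$time_s, df$angle_deg)
}

#' Per-sample binary trust labels for the earth-frame-only estimate
#'
#' `efcorrect` marks samples where the earth-frame-only inclination agrees
#' with the reference within the threshold; `efcorrect_s5` additionally
#' requires the five consecutive samples centred on the sample (truncated at
#' the series ends) to all agree, so `efcorrect_s5 == 1` implies
#' `efcorrect == 1`.
#'
#' @param time_s timestamps in seconds.
#' @param efcorrect,efcorrect_s5 binary (0/1) integer vectors.
#' @return a `label_series` data.frame.
#' @export
label_series <- function(time_s, efcorrect, efcorrect_s5) {
  stopifnot(length(time_s) == length(efcorrect),
            length(time_s) == length(efcorrect_s5))
  if (!all(efcorrect %in% c(0L, 1L)) || !all(efcorrect_s5 %in% c(0L, 1L))) {
    stop("labels must be binary", call. = FALSE)
  }
  if (any(efcorrect_s5 == 1L & efcorrect == 0L)) {
    stop("efcorrect_s5 must imply efcorrect", call. = FALSE)
  }
  structure(data.frame(time_s = time_s, efcorrect = as.integer(efcorrect),
                       efcorrect_s5 = as.integer(efcorrect_s5)),
            class = c("label_series", "data.frame"))
}

#' @rdname label_series
#' @param x a `label_series`.
#' @param path file path.
#' @export
write_label_csv <- function(x, path) {
  stopifnot(inherits(x, "label_series"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname label_series
#' @export
read_label_csv <- function(path) {
  df <- utils::read.csv(path)
  label_series(df$time_s, df$efcorrect, df$efcorrect_s5)
}

#' @export
print.label_series <- function(x, ...) {
  cat(sprintf("<label_series> %d samples, %.1f%% trusted (%.1f%% S5)\n",
              nrow(x), 100 * mean(x$efcorrect), 100 * mean(x$efcorrect_s5)))
  invisible(x)
}
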