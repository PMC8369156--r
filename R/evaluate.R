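# Agreement between IMU-derived and reference inclination: mean error,
# MAE, RMSE, Pearson correlation and Bland-Altman limits of agreement,
# with partitioning into fixed-/free-wheelchair and activity conditions.

#' Agreement metrics between an estimated and a reference angle series
#'
#' Computes the mean error (`mean(est - ref)`), mean absolute error, root
#' mean squared error, Pearson correlation and the Bland-Altman mean
#' difference with 95% limits of agreement (`mean +/- 1.96 sd` of the
#' differences) over the masked samples.
#'
#' Degenerate cases are flagged rather than silently `NaN`: when the
#' difference series is constant the correlation of the two identical
#' shapes is reported as 1 with `constant_difference = TRUE`; when either
#' input is constant the correlation is `NA` with `r_defined = FALSE`.
#'
#' @param est,ref aligned `inclination_series` or numeric vectors, degrees.
#' @param mask optional logical vector selecting samples (at least 30).
#' @param condition label stored in the report.
#' @return an `agreement_report` list: `condition`, `n`, `mean_error`,
#'   `mae`, `rmse`, `pearson_r`, `bland_altman_mean`,
#'   `bland_altman_loa_low`, `bland_altman_loa_high`, plus the degeneracy
#'   flags.
#' @export
agreement <- function(est, ref, mask = NULL, condition = "all") {
  a <- angle_vector(est); b <- angle_vector(ref)
  stopifnot(length(a) == length(b))
  if (is.null(mask)) mask <- rep(TRUE, length(a))
  keep <- mask & !is.na(a) & !is.na(b)
  if (sum(keep) < 30) stop("mask must select at least 30 samples", call. = FALSE)
  a <- a[keep]; b <- b[keep]
  d <- a - b
  sd_d <- stats::sd(d)
  constant_difference <- sd_d < 1e-12
  r_defined <- stats::sd(a) > 0 && stats::sd(b) > 0
  r <- if (constant_difference) {
    1
  } else if (r_defined) {
    stats::cor(a, b)
  } else {
    NA_real_
  }
  structure(list(
    condition = condition, n = length(d),
    mean_error = mean(d), mae = mean(abs(d)), rmse = sqrt(mean(d^2)),
    pearson_r = r,
    bland_altman_mean = mean(d),
    bland_altman_loa_low = mean(d) - 1.96 * sd_d,
    bland_altman_loa_high = mean(d) + 1.96 * sd_d,
    constant_difference = constant_difference, r_defined = r_defined
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> %s (n=%d): ME %.2f, MAE %.2f, RMSE %.2f deg, r %.3f, BA %.2f [%.2f, %.2f]\n",
    x$condition, x$n, x$mean_error, x$mae, x$rmse, x$pearson_r,
    x$bland_altman_mean, x$bland_altman_loa_low, x$bland_altman_loa_high))
  invisible(x)
}

#' Condition masks from segment annotations
#'
#' From simulator annotations (data.frame with `time_s` and `kind`) or a
#' user-supplied segment table (data.frame with `start_s`, `end_s`,
#' `kind`), builds boolean masks per activity kind plus the composite
#' conditions: `free_wheelchair` (sprints, turns and collisions — the
#' wheelchair can move) and `fixed_wheelchair` (its complement: static
#' pose, isolated trunk rotations, ball handling with blocked wheels).
#'
#' @param annotations per-sample annotations, or `NULL` with `segments`.
#' @param segments segment table; rows must not overlap.
#' @param time_s sample times, required with `segments`.
#' @return named list of logical masks (`all`, `fixed_wheelchair`,
#'   `free_wheelchair`, `sprint`, `agility`, and one per kind present).
#' @export
partition_masks <- function(annotations = NULL, segments = NULL,
                            time_s = NULL) {
  if (is.null(annotations)) {
    if (is.null(segments) || is.null(time_s)) {
      stop("unannotated session: supply an explicit segment table and time_s",
           call. = FALSE)
    }
    o <- order(segments$start_s)
    segments <- segments[o, ]
    if (nrow(segments) > 1 &&
        any(segments$start_s[-1] < segments$end_s[-nrow(segments)] - 1e-9)) {
      stop("segments overlap", call. = FALSE)
    }
    kind <- rep(NA_character_, length(time_s))
    for (i in seq_len(nrow(segments))) {
      kind[time_s >= segments$start_s[i] & time_s < segments$end_s[i]] <-
        segments$kind[i]
    }
    annotations <- data.frame(time_s = time_s, kind = kind)
  }
  kind <- annotations$kind
  free_kinds <- c("sprint", "turn", "collision")
  agility_kinds <- c("turn")
  masks <- list(
    all = !is.na(kind),
    fixed_wheelchair = !is.na(kind) & !(kind %in% free_kinds),
    free_wheelchair = !is.na(kind) & kind %in% free_kinds,
    sprint = !is.na(kind) & kind == "sprint",
    agility = !is.na(kind) & kind %in% agility_kinds
  )
  for (k in unique(kind[!is.na(kind)])) {
    masks[[k]] <- !is.na(kind) & kind == k
  }
  masks
}

#' Agreement table for several filters and conditions
#'
#' The condition-by-filter report: one row per (condition, filter) with the
#' agreement metrics, mirroring the standard comparison layout.
#'
#' @param estimates named list of `inclination_series` (e.g.
#'   `list(original = ..., extended = ...)`).
#' @param ref reference `inclination_series`.
#' @param masks named list of logical masks (see [partition_masks()]);
#'   conditions whose mask selects fewer than 30 samples are skipped.
#' @return data.frame with columns `condition`, `filter`, `n`,
#'   `mean_error`, `mae`, `rmse`, `pearson_r`, `ba_loa_low`, `ba_loa_high`.
#' @export
agreement_table <- function(estimates, ref,
                            masks = list(all = NULL)) {
  rows <- list()
  for (cond in names(masks)) {
    for (flt in names(estimates)) {
      rep_ <- tryCatch(
        agreement(estimates[[flt]], ref, mask = masks[[cond]],
                  condition = cond),
        error = function(e) NULL)
      if (is.null(rep_)) next
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, filter = flt, n = rep_$n,
        mean_error = rep_$mean_error, mae = rep_$mae, rmse = rep_$rmse,
        pearson_r = rep_$pearson_r,
        ba_loa_low = rep_$bland_altman_loa_low,
        ba_loa_high = rep_$bland_altman_loa_high
      )
    }
  }
  do.call(rbind, rows)
}
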