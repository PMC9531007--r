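#' Scores inside a trailing day window
#'
#' All scores whose context end date lies in the half-open window
#' `(t - window_days, t]`; the current context's own score is included.
#'
#' @param scores Score tibble (`end_date`, `score`).
#' @param t Window end date.
#' @param window_days Window length in days.
#'
#' @return Numeric vector of in-window scores.
#' @export
window_scores <- function(scores, t, window_days) {
  t <- as.Date(t)
  sel <- scores$end_date > t - window_days & scores$end_date <= t
  scores$score[sel]
}

#' Sliding-window outlier flags
#'
#' Three rules deciding whether the current score is anomalous relative to
#' its trailing window:
#' * `robust_z_flag()`: modified z-score `0.6745 * (current - median) / MAD`
#'   exceeds `z_thr`; when the window MAD is 0 the rule degenerates to a
#'   conservative median-exceedance test (`current > median`).
#' * `iqr_flag()`: Tukey fence, `current > Q3 + iqr_thr * (Q3 - Q1)` with
#'   quartiles by linear interpolation.
#' * `quantile_flag()`: `current >` the `q_thr` empirical quantile of the
#'   window (linear interpolation).
#'
#' All comparisons are strict; windows smaller than `min_count` never flag.
#'
#' @param window Numeric vector of in-window scores (including the current
#'   one).
#' @param current The score being tested.
#' @param z_thr,iqr_thr,q_thr Rule thresholds.
#' @param min_count Minimum window occupancy (default 3).
#'
#' @return Logical flag. For `robust_z_flag` the result carries an attribute
#'   `degenerate = TRUE` when the MAD-zero fallback was used.
#' @export
robust_z_flag <- function(window, current, z_thr, min_count = 3) {
  if (length(window) < min_count) return(FALSE)
  med <- median(window)
  mad0 <- median(abs(window - med))
  if (mad0 == 0) {
    return(structure(current > med, degenerate = TRUE))
  }
  0.6745 * (current - med) / mad0 > z_thr
}

#' @rdname robust_z_flag
#' @export
iqr_flag <- function(window, current, iqr_thr, min_count = 3) {
  if (length(window) < min_count) return(FALSE)
  q <- quantile(window, c(0.25, 0.75), names = FALSE, type = 7)
  current > q[2] + iqr_thr * (q[2] - q[1])
}

#' @rdname robust_z_flag
#' @export
quantile_flag <- function(window, current, q_thr, min_count = 3) {
  if (length(window) < min_count) return(FALSE)
  current > quantile(window, q_thr, names = FALSE, type = 7)
}

# thresholding grid used throughout the experiments
.table_grid <- list(
  window_days = c(7, 14, 21, 30, 60, 90),
  z_thr = c(1.65, 1.8, 3, 4),
  iqr_thr = c(1.0, 1.2),
  q_thr = c(0.95, 0.96, 0.97, 0.98)
)

#' The standard thresholding grid
#'
#' Every combination of thresholding method, sliding-window length (7, 14,
#' 21, 30, 60, 90 days) and threshold (robust z: 1.65, 1.8, 3, 4; IQR: 1.0,
#' 1.2; quantile: 0.95-0.98) evaluated in the experiments.
#'
#' @return Tibble `method`, `window_days`, `threshold`.
#' @export
threshold_grid <- function() {
  dplyr::bind_rows(
    tidyr::expand_grid(method = "robust_z", window_days = .table_grid$window_days,
                       threshold = .table_grid$z_thr),
    tidyr::expand_grid(method = "iqr", window_days = .table_grid$window_days,
                       threshold = .table_grid$iqr_thr),
    tidyr::expand_grid(method = "quantile", window_days = .table_grid$window_days,
                       threshold = .table_grid$q_thr)
  )
}

#' Broadcast context scores to a daily score series
#'
#' In the streaming setting the anomaly score current on day d is the score
#' of the most recent fully scored context (end date <= d), so the daily
#' series is piecewise constant and advances once per context stride. This
#' is the day-denominated series thresholding operates on, putting the
#' context-based models on the same footing as methods that score each day
#' directly.
#'
#' @param scores Score tibble for one patient (`context_id`, `end_date`,
#'   `score`), date-ordered.
#'
#' @return Tibble `date`, `context_id`, `score`, one row per day from the
#'   first to the last context end date.
#' @export
daily_scores <- function(scores) {
  scores <- dplyr::arrange(scores, .data$end_date)
  if (nrow(scores) == 0) {
    return(tibble::tibble(date = as.Date(character()), context_id = integer(),
                          score = numeric()))
  }
  days <- seq(min(scores$end_date), max(scores$end_date), by = "day")
  idx <- findInterval(as.numeric(days), as.numeric(scores$end_date))
  tibble::tibble(date = days, context_id = scores$context_id[idx],
                 score = scores$score[idx])
}

#' Detect anomalous days by sliding-window thresholding
#'
#' Context scores are broadcast to a daily piecewise-constant series
#' (see [daily_scores()]); every day is then tested against the trailing
#' `window_days` daily values (current day included, membership in
#' `(t - window_days, t]`). Flagged days become alerts, so alert counts are
#' day-denominated. Off-grid window or threshold values are accepted with a
#' warning.
#'
#' @param scores Score tibble (`patient_id` optional, `context_id`,
#'   `end_date`, `score`).
#' @param method `"robust_z"`, `"iqr"` or `"quantile"`.
#' @param window_days Sliding window length in days.
#' @param threshold Rule threshold (z, IQR multiple, or quantile).
#' @param min_window_count Minimum in-window values before any flag is
#'   raised (default 3); avoids start-of-series false alerts where MAD/IQR
#'   are undefined.
#'
#' @return Alert tibble: `patient_id`, `context_id` (the context whose score
#'   fired), `end_date` (the flagged day), `score`, `method`, `window_days`,
#'   `threshold`.
#' @export
detect <- function(scores, method = c("robust_z", "iqr", "quantile"),
                   window_days = 7, threshold = 1.65, min_window_count = 3) {
  method <- match.arg(method)
  ok <- switch(method,
    robust_z = threshold %in% .table_grid$z_thr,
    iqr = threshold %in% .table_grid$iqr_thr,
    quantile = threshold %in% .table_grid$q_thr
  )
  if (!window_days %in% .table_grid$window_days || !ok) {
    warn("window/threshold outside the standard grid; proceeding anyway")
  }
  if (!"patient_id" %in% names(scores)) {
    scores <- dplyr::mutate(scores, patient_id = "P001")
  }
  flag_fun <- switch(method, robust_z = robust_z_flag, iqr = iqr_flag,
                     quantile = quantile_flag)
  res <- scores |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      dd <- daily_scores(df)
      degenerate <- FALSE
      flags <- vapply(seq_len(nrow(dd)), function(i) {
        sel <- dd$date > dd$date[i] - window_days & dd$date <= dd$date[i]
        # baseline guard: the window must span enough distinct context
        # scores, not merely enough broadcast days
        if (length(unique(dd$context_id[sel])) < min_window_count) {
          return(FALSE)
        }
        fl <- flag_fun(dd$score[sel], dd$score[i], threshold,
                       min_count = min_window_count)
        if (isTRUE(attr(fl, "degenerate"))) degenerate <<- TRUE
        as.logical(fl)
      }, logical(1))
      if (degenerate) {
        warn("zero-MAD window(s) encountered; used median-exceedance fallback")
      }
      dplyr::tibble(context_id = dd$context_id[flags],
                    end_date = dd$date[flags], score = dd$score[flags])
    }) |>
    dplyr::ungroup()
  dplyr::mutate(res, method = method, window_days = window_days,
                threshold = threshold)
}
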