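#' Match alerts against weak labels with a soft buffer
#'
#' A label on day L is considered recalled if at least one alert falls in
#' the closed interval `[L - buffer_before, L + buffer_after]` (default -10
#' to +7 days, absorbing the unclear onset of the labelled condition and
#' rewarding early detection). An alert is a true positive if it matches at
#' least one label; one alert may validate several labels and several alerts
#' may validate one label (counted once).
#'
#' @param alerts Alert tibble with `end_date` (and optionally `patient_id`).
#' @param labels Label tibble with `date` (and optionally `patient_id`,
#'   `type`). Both inputs should belong to the same patient, or carry
#'   matching `patient_id` columns.
#' @param buffer_before,buffer_after Soft buffer in days (defaults 10, 7).
#'
#' @return List with `labels` (input plus `n_matching_alerts`, `recalled`)
#'   and `alerts` (input plus `n_matching_labels`, `true_positive`).
#' @export
match_alerts <- function(alerts, labels, buffer_before = 10, buffer_after = 7) {
  stopifnot(buffer_before >= 0, buffer_after >= 0)
  has_pid <- "patient_id" %in% names(alerts) && "patient_id" %in% names(labels)
  pair_ok <- function(a_pid, l_pid) if (has_pid) a_pid == l_pid else TRUE
  n_match_lab <- integer(nrow(labels))
  n_match_al <- integer(max(nrow(alerts), 0))
  if (nrow(alerts) && nrow(labels)) {
    for (li in seq_len(nrow(labels))) {
      L <- labels$date[li]
      hit <- alerts$end_date >= L - buffer_before &
        alerts$end_date <= L + buffer_after
      if (has_pid) hit <- hit & alerts$patient_id == labels$patient_id[li]
      n_match_lab[li] <- sum(hit)
      n_match_al[hit] <- n_match_al[hit] + 1L
    }
  }
  list(
    labels = dplyr::mutate(labels, n_matching_alerts = n_match_lab,
                           recalled = n_match_lab > 0),
    alerts = dplyr::mutate(alerts, n_matching_labels = n_match_al,
                           true_positive = n_match_al > 0)
  )
}

#' Per-patient evaluation metrics
#'
#' Recall (% of labels recalled), alerts raised, alert rate (% of observed
#' days carrying an alert, the day-denominated rate reported for this kind
#' of monitoring), and precision (% of alerts that match a label; of limited
#' absolute meaning since only two event types are labelled, so it should be
#' read relatively across models).
#'
#' @inheritParams match_alerts
#' @param observed_days Number of observed (non-padded) days for the
#'   patient.
#' @param patient_id Optional identifier for the output row.
#'
#' @return One-row tibble: `patient_id`, `n_labels`, `n_recalled`, `recall`,
#'   `n_alerts`, `n_true_positive`, `observed_days`, `alert_rate`,
#'   `precision`. `recall` is `NA` when the patient has no labels,
#'   `precision` is `NA` when no alerts were raised.
#' @export
evaluate_patient <- function(alerts, labels, observed_days,
                             buffer_before = 10, buffer_after = 7,
                             patient_id = NULL) {
  stopifnot(observed_days > 0)
  mt <- match_alerts(alerts, labels, buffer_before, buffer_after)
  n_lab <- nrow(labels)
  n_rec <- sum(mt$labels$recalled)
  n_al <- nrow(alerts)
  n_tp <- sum(mt$alerts$true_positive)
  pid <- patient_id %||%
    (if ("patient_id" %in% names(labels) && n_lab) labels$patient_id[1]
     else if ("patient_id" %in% names(alerts) && n_al) alerts$patient_id[1]
     else NA_character_)
  tibble::tibble(
    patient_id = pid,
    n_labels = n_lab, n_recalled = n_rec,
    recall = if (n_lab > 0) 100 * n_rec / n_lab else NA_real_,
    n_alerts = n_al, n_true_positive = n_tp,
    observed_days = observed_days,
    alert_rate = 100 * n_al / observed_days,
    precision = if (n_al > 0) 100 * n_tp / n_al else NA_real_
  )
}

#' Cohort-level evaluation report
#'
#' Aggregates per-patient metrics into unweighted cohort means, counts the
#' patients whose recall strictly exceeds the threshold (default one-third:
#' with roughly 3 labels per patient this asks whether more than one of a
#' patient's events was caught), and reports the labelled-day fraction of
#' the cohort.
#'
#' @param per_patient Tibble of rows from [evaluate_patient()].
#' @param recall_patient_threshold Fraction (default 1/3); the patient count
#'   uses strict `>`.
#'
#' @return Object of class `cmpad_eval`: list with `per_patient` and a
#'   one-row `cohort` tibble (`mean_recall`, `mean_alerts`,
#'   `mean_alert_rate`, `patients_above_threshold`, `n_evaluable`,
#'   `precision`, `total_labels`, `total_days`, `label_rate_pct`). Patients
#'   without labels are excluded from recall aggregates (with a note);
#'   patients without alerts are excluded from the precision mean.
#' @export
evaluate_cohort <- function(per_patient, recall_patient_threshold = 1 / 3) {
  ev <- per_patient[!is.na(per_patient$recall), , drop = FALSE]
  if (nrow(ev) == 0) abort("no evaluable patients", class = "cmpad_input_error")
  if (nrow(ev) < nrow(per_patient)) {
    inform(paste0(nrow(per_patient) - nrow(ev),
                  " patient(s) without labels excluded from recall aggregates"))
  }
  cohort <- tibble::tibble(
    mean_recall = mean(ev$recall),
    mean_alerts = mean(per_patient$n_alerts),
    mean_alert_rate = mean(per_patient$alert_rate),
    # strict "greater than"; nudge the cut so that a recall of exactly the
    # threshold fraction never counts (100 * (1/3) floats below 100/3)
    patients_above_threshold = sum(ev$recall > 100 * recall_patient_threshold + 1e-9),
    n_evaluable = nrow(ev),
    precision = if (any(!is.na(per_patient$precision)))
      mean(per_patient$precision, na.rm = TRUE) else NA_real_,
    total_labels = sum(per_patient$n_labels),
    total_days = sum(per_patient$observed_days),
    label_rate_pct = 100 * sum(per_patient$n_labels) /
      sum(per_patient$observed_days)
  )
  structure(list(per_patient = per_patient, cohort = cohort),
            class = "cmpad_eval")
}

#' @export
print.cmpad_eval <- function(x, ...) {
  cat("<cmpad_eval> ", nrow(x$per_patient), " patients\n", sep = "")
  print(x$cohort)
  invisible(x)
}

#' @describeIn evaluate_cohort `tidy()` returns the per-patient table.
#' @param x A `cmpad_eval` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cmpad_eval <- function(x, ...) x$per_patient

#' @describeIn evaluate_cohort `glance()` returns the one-row cohort
#'   summary.
#' @exportS3Method generics::glance
glance.cmpad_eval <- function(x, ...) x$cohort

#' Exhaustive threshold grid search
#'
#' Scores every patient once per model, then evaluates every thresholding
#' setting in the grid, returning the full results table and the best
#' setting per model ("best" = highest mean recall, ties broken by fewer
#' mean alerts, then by smaller window).
#'
#' @param features Multi-patient feature tibble.
#' @param labels Multi-patient label tibble.
#' @param models Character vector of [score_pipeline()] model tags.
#' @param grid Tibble from [threshold_grid()] (or a subset).
#' @param ... Passed to [score_pipeline()] (e.g. `m`, `c`, `k`).
#'
#' @return List with `best` (one row per model) and `results` (the full
#'   grid), both carrying the cohort metrics.
#' @export
grid_search <- function(features, labels, models = "mdcmp_equal",
                        grid = threshold_grid(), ...) {
  stopifnot(nrow(grid) >= 1)
  obs <- features |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(observed_days = sum(!.data$missing), .groups = "drop")
  rows <- list()
  for (mod in models) {
    scores <- score_pipeline(features, model = mod, ...)
    for (g in seq_len(nrow(grid))) {
      alerts <- suppressWarnings(
        detect(scores, method = grid$method[g],
               window_days = grid$window_days[g], threshold = grid$threshold[g])
      )
      pp <- purrr::map_dfr(obs$patient_id, function(pid) {
        evaluate_patient(
          dplyr::filter(alerts, .data$patient_id == pid),
          dplyr::filter(labels, .data$patient_id == pid),
          observed_days = obs$observed_days[obs$patient_id == pid],
          patient_id = pid
        )
      })
      co <- suppressMessages(evaluate_cohort(pp))$cohort
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(model = mod, method = grid$method[g],
                       window_days = grid$window_days[g],
                       threshold = grid$threshold[g]),
        co
      )
    }
  }
  results <- dplyr::bind_rows(rows)
  best <- results |>
    dplyr::group_by(.data$model) |>
    dplyr::arrange(dplyr::desc(.data$mean_recall), .data$mean_alerts,
                   .data$window_days, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
  list(best = best, results = results)
}
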