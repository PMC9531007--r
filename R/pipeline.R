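#' Validate a YAML run configuration
#'
#' Reads (or takes) a configuration list, fills defaults, and
#' cross-validates the values. Defaults reproduce the standard experimental
#' settings: context window 3, subsequence length 3 days, the full
#' thresholding grid, entropy parameters N = 500 / r = 0.2 / m = 7, and the
#' -10/+7-day soft buffer. Off-grid threshold values are accepted with a
#' warning; structurally impossible values (e.g. `m = 1`, for which
#' z-normalization is undefined) are rejected.
#'
#' @param x Path to a YAML file, a list, or `NULL` for pure defaults.
#'
#' @return A validated configuration list of class `cmpad_config`.
#' @export
validate_config <- function(x = NULL) {
  raw <- if (is.null(x)) list()
  else if (is.character(x)) yaml::read_yaml(x) %||% list()
  else if (is.list(x)) x
  else abort("config must be a path, list or NULL", class = "cmpad_config_error")

  def <- list(
    m = 3, c = 3, exclusion = "mp_half_m",
    model = "mdcmp_equal", k = "auto",
    method = "robust_z", window_days = 7, threshold = 1.65,
    min_window_count = 3,
    entropy = list(n_max = 500, r = 0.2, m_e = 7, n_fuzzy = 2),
    buffer_before = 10, buffer_after = 7,
    recall_patient_threshold = 1 / 3,
    counts = "visits", duration_rule = "gap",
    seed = 1
  )
  cfg <- utils::modifyList(def, raw)
  if (cfg$m < 2) abort("m must be >= 2 (z-normalization undefined for m = 1)",
                       class = "cmpad_config_error")
  if (cfg$c < 1) abort("c must be >= 1", class = "cmpad_config_error")
  if (!cfg$model %in% c("sum", "mean", "median", "max", "apen", "fuzzyen",
                        "mdcmp_equal", "mdcmp_distance")) {
    abort(paste0("unknown model: ", cfg$model), class = "cmpad_config_error")
  }
  if (!cfg$method %in% c("robust_z", "iqr", "quantile")) {
    abort(paste0("unknown thresholding method: ", cfg$method),
          class = "cmpad_config_error")
  }
  ongrid <- cfg$window_days %in% .table_grid$window_days &&
    cfg$threshold %in% switch(cfg$method, robust_z = .table_grid$z_thr,
                              iqr = .table_grid$iqr_thr,
                              quantile = .table_grid$q_thr)
  if (!ongrid) warn("window/threshold outside the standard grid")
  if (!identical(cfg$k, "auto")) {
    cfg$k <- as.integer(cfg$k)
    if (is.na(cfg$k) || cfg$k < 0) abort("k must be 'auto' or a non-negative integer",
                                         class = "cmpad_config_error")
  }
  structure(cfg, class = "cmpad_config")
}

#' Run the full anomaly-detection pipeline
#'
#' Events to features to CMPs to scores to alerts to evaluation to
#' biomarkers, with every stage persisted as CSV when `out_dir` is given.
#' Given a fixed configuration and input, reruns are byte-identical.
#'
#' @param events Event tibble (`patient_id`, `timestamp`, `location`).
#' @param labels Label tibble (`patient_id`, `date`, `type`).
#' @param config A `cmpad_config` (see [validate_config()]), a list, a YAML
#'   path, or `NULL` for defaults.
#' @param out_dir Optional output directory for stage CSVs
#'   (`features.csv`, `scores.csv`, `alerts.csv`, `evaluation_patients.csv`,
#'   `evaluation_cohort.csv`, `biomarkers_patients.csv`,
#'   `biomarkers_cohort.csv`) and the resolved `config.yaml`.
#'
#' @return List with `features`, `scores`, `alerts`, `evaluation`
#'   (`cmpad_eval`), `biomarkers` (per patient) and `biomarkers_cohort`.
#' @export
run_pipeline <- function(events, labels, config = NULL, out_dir = NULL) {
  cfg <- if (inherits(config, "cmpad_config")) config else validate_config(config)

  features <- build_feature_series(events, counts = cfg$counts,
                                   duration_rule = cfg$duration_rule)
  scores <- score_pipeline(features, model = cfg$model, m = cfg$m, c = cfg$c,
                           k = cfg$k, exclusion = cfg$exclusion,
                           m_e = cfg$entropy$m_e, r = cfg$entropy$r,
                           n_fuzzy = cfg$entropy$n_fuzzy,
                           n_max = cfg$entropy$n_max)
  alerts <- detect(scores, method = cfg$method, window_days = cfg$window_days,
                   threshold = cfg$threshold,
                   min_window_count = cfg$min_window_count)

  obs <- features |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(observed_days = sum(!.data$missing), .groups = "drop")
  per_patient <- purrr::map_dfr(obs$patient_id, function(pid) {
    evaluate_patient(
      dplyr::filter(alerts, .data$patient_id == pid),
      dplyr::filter(labels, .data$patient_id == pid),
      observed_days = obs$observed_days[obs$patient_id == pid],
      buffer_before = cfg$buffer_before, buffer_after = cfg$buffer_after,
      patient_id = pid
    )
  })
  evaluation <- suppressMessages(
    evaluate_cohort(per_patient, cfg$recall_patient_threshold)
  )

  bios <- purrr::map_dfr(obs$patient_id, function(pid) {
    fp <- dplyr::filter(features, .data$patient_id == pid)
    stk <- patient_stack(fp, m = cfg$m, c = cfg$c, exclusion = cfg$exclusion)
    k_used <- scores$k_used[scores$patient_id == pid][1]
    if (is.na(k_used)) k_used <- 0L
    biomarker_contributions(stk, k_used = k_used, patient_id = pid)
  })
  bio_cohort <- cohort_biomarkers(bios)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_csv(features, file.path(out_dir, "features.csv"))
    readr::write_csv(scores, file.path(out_dir, "scores.csv"))
    readr::write_csv(alerts, file.path(out_dir, "alerts.csv"))
    readr::write_csv(per_patient, file.path(out_dir, "evaluation_patients.csv"))
    readr::write_csv(evaluation$cohort, file.path(out_dir, "evaluation_cohort.csv"))
    readr::write_csv(bios, file.path(out_dir, "biomarkers_patients.csv"))
    readr::write_csv(bio_cohort, file.path(out_dir, "biomarkers_cohort.csv"))
    yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  }
  list(features = features, scores = scores, alerts = alerts,
       evaluation = evaluation, biomarkers = bios,
       biomarkers_cohort = bio_cohort)
}

#' Read stage CSVs written by the pipeline
#'
#' Round-trip readers for the CSV dialects the pipeline writes, with column
#' types pinned so downstream stages parse losslessly.
#'
#' @param path File path.
#' @name cmpad_io
#' @export
read_events_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    timestamp = readr::col_datetime(),
    location = readr::col_character()
  ))
}

#' @rdname cmpad_io
#' @export
read_labels_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    date = readr::col_date(),
    type = readr::col_character()
  ))
}
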