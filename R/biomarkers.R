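#' Digital-biomarker contributions from a stacked CMP
#'
#' The sorted stack records which feature supplied each of the smallest
#' distances per context pair. The contribution of a feature is the fraction
#' of finite upper-triangle (dimension <= `k_used`) slots it occupies; the
#' modal feature of dimension 0 is the patient's top biomarker (ties broken
#' lexicographically).
#'
#' @param stacked A `cmp_stack` (see [stack_cmps()], [patient_stack()]).
#' @param k_used Zero-based dimension cut-off, normally the `k` used for
#'   scoring.
#' @param dims `"top1"` (default: dimension 0 only, so the ranking follows
#'   the modal most-similar feature that drives the minimum-distance score)
#'   or `"leq_k"` (count dimensions 0..k_used).
#' @param patient_id Optional identifier attached to the output.
#'
#' @return Tibble `patient_id`, `feature`, `contribution` (fractions summing
#'   to 1), `top_biomarker` (logical, TRUE on the modal dimension-0
#'   feature's row), sorted by decreasing contribution.
#' @export
biomarker_contributions <- function(stacked, k_used, dims = c("top1", "leq_k"),
                                    patient_id = NA_character_) {
  stopifnot(inherits(stacked, "cmp_stack"))
  dims <- match.arg(dims)
  F <- dim(stacked$values)[1]
  if (k_used < 0 || k_used >= F) abort("k_used out of range",
                                       class = "cmpad_input_error")
  C <- dim(stacked$values)[2]
  ut <- upper.tri(matrix(0, C, C))
  kk <- if (dims == "top1") 1L else seq_len(k_used + 1L)
  slots <- character(0)
  for (d in kk) {
    v <- stacked$values[d, , ][ut]
    f <- stacked$feature_order[d, , ][ut]
    slots <- c(slots, f[is.finite(v)])
  }
  counts <- table(factor(slots, levels = stacked$features))
  contrib <- as.numeric(counts) / max(sum(counts), 1)
  # modal feature in dimension 0
  d0v <- stacked$values[1, , ][ut]
  d0f <- stacked$feature_order[1, , ][ut][is.finite(d0v)]
  d0tab <- table(factor(d0f, levels = stacked$features))
  top <- stacked$features[which.max(d0tab)]  # ties -> first in lex order
  tibble::tibble(
    patient_id = patient_id,
    feature = stacked$features,
    contribution = contrib,
    top_biomarker = stacked$features == top
  ) |> dplyr::arrange(dplyr::desc(.data$contribution), .data$feature)
}

#' Cohort-level biomarker ranking
#'
#' Median per-feature contribution across patients, ranked descending, plus
#' the count of patients for which each feature is the top biomarker.
#'
#' @param reports Per-patient tibbles from [biomarker_contributions()]
#'   (a list or a pre-bound tibble).
#'
#' @return Tibble `feature`, `median_contribution`, `n_top_patients`, ranked
#'   by decreasing median contribution (ties by feature name).
#' @export
cohort_biomarkers <- function(reports) {
  df <- if (is.data.frame(reports)) reports else dplyr::bind_rows(reports)
  stopifnot(nrow(df) >= 1)
  df |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(median_contribution = median(.data$contribution),
                     n_top_patients = sum(.data$top_biomarker),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$median_contribution), .data$feature)
}

#' Bar chart of cohort biomarker contributions
#'
#' @param cohort Tibble from [cohort_biomarkers()].
#'
#' @return A ggplot object.
#' @export
plot_biomarkers <- function(cohort) {
  ggplot2::ggplot(cohort,
                  ggplot2::aes(x = stats::reorder(.data$feature,
                                                  .data$median_contribution),
                               y = 100 * .data$median_contribution)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "median contribution to anomaly score (%)") +
    ggplot2::theme_minimal()
}

#' Score series plot with alerts and labels
#'
#' Line plot of a patient's anomaly scores with flagged contexts and weak
#' label dates overlaid.
#'
#' @param scores Score tibble for one patient.
#' @param alerts Optional alert tibble.
#' @param labels Optional label tibble.
#'
#' @return A ggplot object.
#' @export
plot_scores <- function(scores, alerts = NULL, labels = NULL) {
  p <- ggplot2::ggplot(scores, ggplot2::aes(x = .data$end_date,
                                            y = .data$score)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::labs(x = "context end date", y = "anomaly score") +
    ggplot2::theme_minimal()
  if (!is.null(labels) && nrow(labels)) {
    p <- p + ggplot2::geom_vline(data = labels,
                                 ggplot2::aes(xintercept = .data$date),
                                 linetype = "dashed", colour = "firebrick")
  }
  if (!is.null(alerts) && nrow(alerts)) {
    p <- p + ggplot2::geom_point(data = alerts, colour = "firebrick", size = 2)
  }
  p
}
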