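#' Context anomaly scores from a CMP layer
#'
#' The anomaly score of a context is the average of its minimum distances to
#' strictly earlier contexts (streaming contract: only historical data is
#' used, so the first context is never scored). Equal weighting averages all
#' finite past cells; distance weighting down-weights a past context by its
#' hop distance, so a context 3 hops back contributes with weight 1/3.
#'
#' @param cmp_layer C x C numeric matrix (a CMP or one k-dimensional layer).
#' @param i Context index (1-based); must be >= 2.
#'
#' @return The score, or `NA` when no finite past cell exists.
#' @export
context_score_equal <- function(cmp_layer, i) {
  if (i < 2) return(NA_real_)
  past <- cmp_layer[i, seq_len(i - 1)]
  past <- past[is.finite(past)]
  if (!length(past)) return(NA_real_)
  mean(past)
}

#' @rdname context_score_equal
#' @export
context_score_distance_weighted <- function(cmp_layer, i) {
  if (i < 2) return(NA_real_)
  j <- seq_len(i - 1)
  d <- cmp_layer[i, j]
  w <- 1 / (i - j)
  fin <- is.finite(d)
  if (!any(fin)) return(NA_real_)
  sum(w[fin] * d[fin]) / sum(w[fin])
}

# one dated score per context from a CMP layer
.score_series <- function(cmp, weighting = c("equal", "distance")) {
  weighting <- match.arg(weighting)
  f <- if (weighting == "equal") context_score_equal else context_score_distance_weighted
  C <- nrow(cmp$values)
  s <- vapply(seq_len(C), function(i) f(cmp$values, i), numeric(1))
  tibble::tibble(
    context_id = cmp$contexts$context_id,
    end_date = cmp$contexts$end_date,
    score = s
  ) |> dplyr::filter(!is.na(.data$score))
}

#' Fuse per-feature anomaly score series
#'
#' Combines univariate (per-feature) score series into a single score per
#' context by the named statistic. Entropy-based methods use the supplied
#' inverse-entropy weights in a weighted sum.
#'
#' @param per_feature_scores Named list of score tibbles (`context_id`,
#'   `end_date`, `score`) on a common context grid.
#' @param method One of `"sum"`, `"mean"`, `"median"`, `"max"`, `"apen"`,
#'   `"fuzzyen"`.
#' @param weights Named weight vector (summing to 1) over the features;
#'   required for the entropy methods.
#'
#' @return Score tibble (`context_id`, `end_date`, `score`).
#' @export
fuse_univariate <- function(per_feature_scores,
                            method = c("sum", "mean", "median", "max",
                                       "apen", "fuzzyen"),
                            weights = NULL) {
  method <- match.arg(method)
  grids <- purrr::map(per_feature_scores, "context_id")
  if (length(unique(purrr::map_chr(grids, ~ paste(.x, collapse = ",")))) != 1) {
    abort("per-feature score series are misaligned", class = "cmpad_input_error")
  }
  S <- do.call(cbind, purrr::map(per_feature_scores, "score"))
  base <- per_feature_scores[[1]]
  score <- switch(method,
    sum = rowSums(S),
    mean = rowMeans(S),
    median = apply(S, 1, median),
    max = apply(S, 1, max),
    apen = ,
    fuzzyen = {
      if (is.null(weights)) abort("entropy fusion needs weights",
                                  class = "cmpad_input_error")
      w <- weights[colnames(S) %||% names(per_feature_scores)]
      as.vector(S %*% w)
    }
  )
  tibble::tibble(context_id = base$context_id, end_date = base$end_date,
                 score = score)
}

#' End-to-end anomaly scoring for one or more patients
#'
#' Runs the full scoring pipeline on a daily feature table: per-feature
#' CMPs, then either univariate fusion (`sum`/`mean`/`median`/`max`/
#' entropy-weighted) or the multidimensional CMP route (stack, sort,
#' prefix-mean, pick layer `k` or the kneedle-optimal layer, then
#' equal- or distance-weighted context scoring). Scores are dated by
#' context end day.
#'
#' @param features Feature tibble from [build_feature_series()] (with or
#'   without a `patient_id` column).
#' @param model One of `"sum"`, `"mean"`, `"median"`, `"max"`, `"apen"`,
#'   `"fuzzyen"`, `"mdcmp_equal"`, `"mdcmp_distance"`.
#' @param m,c Subsequence length and context window in days/subsequences
#'   (defaults 3 and 3).
#' @param k `"auto"` (kneedle) or a zero-based integer layer, used by the
#'   mdcmp models.
#' @param exclusion Passed to [cmp_self_join()].
#' @param m_e,r,n_fuzzy,n_max Entropy configuration for the entropy-weighted
#'   models.
#'
#' @return Tibble `patient_id`, `context_id`, `end_date`, `score`, `model`,
#'   `k_used` (`NA` for univariate models).
#' @export
score_pipeline <- function(features,
                           model = c("mdcmp_equal", "mdcmp_distance", "sum",
                                     "mean", "median", "max", "apen", "fuzzyen"),
                           m = 3, c = 3, k = "auto",
                           exclusion = c("mp_half_m", "none"),
                           m_e = 7, r = 0.2, n_fuzzy = 2, n_max = 500) {
  model <- match.arg(model)
  exclusion <- match.arg(exclusion)
  if (!"patient_id" %in% names(features)) {
    features <- dplyr::mutate(features, patient_id = "P001")
  }
  features |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(~ .score_one(.x, model, m, c, k, exclusion,
                                     m_e, r, n_fuzzy, n_max)) |>
    dplyr::ungroup()
}

# per-feature CMPs for one patient's feature table
.patient_cmps <- function(features, m, c, exclusion) {
  dates <- features$date
  cols <- intersect(.cmpad_features, names(features))
  cmps <- purrr::map(cols, ~ cmp_self_join(features[[.x]], m = m, c = c,
                                           dates = dates, exclusion = exclusion,
                                           feature = .x))
  stats::setNames(cmps, cols)
}

#' Stacked CMP for one patient
#'
#' Convenience wrapper: builds all per-feature CMPs for one patient's
#' feature table and stacks them (see [stack_cmps()]); the starting point
#' for both multidimensional scoring and biomarker attribution.
#'
#' @inheritParams score_pipeline
#' @export
patient_stack <- function(features, m = 3, c = 3,
                          exclusion = c("mp_half_m", "none")) {
  exclusion <- match.arg(exclusion)
  if ("patient_id" %in% names(features) &&
      length(unique(features$patient_id)) > 1) {
    abort("patient_stack expects a single patient", class = "cmpad_input_error")
  }
  stack_cmps(.patient_cmps(features, m, c, exclusion))
}

.score_one <- function(features, model, m, c, k, exclusion,
                       m_e, r, n_fuzzy, n_max) {
  if (model %in% c("mdcmp_equal", "mdcmp_distance")) {
    stk <- stack_cmps(.patient_cmps(features, m, c, exclusion))
    kd <- kdim_cmp(stk)
    k_used <- if (identical(k, "auto")) optimal_k(kd) else as.integer(k)
    layer <- select_layer(kd, k_used)
    weighting <- if (model == "mdcmp_equal") "equal" else "distance"
    out <- .score_series(layer, weighting)
  } else {
    cmps <- .patient_cmps(features, m, c, exclusion)
    per_feat <- purrr::map(cmps, .score_series, weighting = "equal")
    w <- NULL
    if (model %in% c("apen", "fuzzyen")) {
      w <- entropy_weights(features, kind = model, m_e = m_e, r = r,
                           n_fuzzy = n_fuzzy, n_max = n_max)
    }
    out <- fuse_univariate(per_feat, method = model, weights = w)
    k_used <- NA_integer_
  }
  dplyr::mutate(out, model = model, k_used = k_used)
}
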