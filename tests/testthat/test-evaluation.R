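mk_alerts <- function(dates) {
  tibble::tibble(context_id = seq_along(dates), end_date = as.Date(dates),
                 score = 1)
}
mk_labels <- function(dates, type = "UTI") {
  tibble::tibble(date = as.Date(dates), type = type)
}

test_that("soft-buffer matching is a closed -10/+7 day interval", {
  lab <- mk_labels("2021-03-15")
  expect_true(match_alerts(mk_alerts("2021-03-05"), lab)$labels$recalled)
  expect_false(match_alerts(mk_alerts("2021-03-04"), lab)$labels$recalled)
  expect_true(match_alerts(mk_alerts("2021-03-22"), lab)$labels$recalled)
  expect_false(match_alerts(mk_alerts("2021-03-23"), lab)$labels$recalled)
  none <- match_alerts(mk_alerts(character(0)), lab)
  expect_false(none$labels$recalled)
  # one alert can validate two labels; two alerts validate one label once
  two_lab <- mk_labels(c("2021-03-15", "2021-03-18"))
  mt <- match_alerts(mk_alerts("2021-03-16"), two_lab)
  expect_equal(mt$labels$recalled, c(TRUE, TRUE))
  expect_equal(mt$alerts$n_matching_labels, 2L)
  mt2 <- match_alerts(mk_alerts(c("2021-03-14", "2021-03-16")), lab)
  expect_equal(sum(mt2$labels$recalled), 1)
})

test_that("per-patient metrics reproduce the headline arithmetic", {
  lab <- mk_labels(c("2021-02-01", "2021-04-01", "2021-06-01"))
  al <- mk_alerts(c("2021-02-03", "2021-04-02", "2021-08-01"))
  ev <- evaluate_patient(al, lab, observed_days = 624)
  expect_equal(ev$recall, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(ev$n_alerts, 3)
  # 32 alerts over 624 days is the 5.1% day-rate worked example
  ev2 <- evaluate_patient(mk_alerts(as.Date("2021-01-01") + seq_len(32) * 7),
                          mk_labels("2021-01-05"), observed_days = 624)
  expect_equal(round(ev2$alert_rate, 1), 5.1)
  # no alerts: precision undefined
  ev3 <- evaluate_patient(mk_alerts(character(0)), lab, observed_days = 100)
  expect_true(is.na(ev3$precision))
  expect_equal(ev3$recall, 0)
  # no labels: recall undefined
  ev4 <- evaluate_patient(al, mk_labels(character(0)), observed_days = 100)
  expect_true(is.na(ev4$recall))
})

test_that("the one-third patient criterion is strict", {
  pp <- dplyr::bind_rows(
    evaluate_patient(mk_alerts(c("2021-02-01", "2021-04-01", "2021-06-01")),
                     mk_labels(c("2021-02-01", "2021-04-01", "2021-06-01")),
                     365, patient_id = "A"),
    evaluate_patient(mk_alerts("2021-02-01"),
                     mk_labels(c("2021-02-01", "2021-04-01", "2021-06-01")),
                     365, patient_id = "B"),
    evaluate_patient(mk_alerts(character(0)),
                     mk_labels(c("2021-02-01", "2021-04-01", "2021-06-01")),
                     365, patient_id = "C")
  )
  ev <- evaluate_cohort(pp)
  # recalls 100, 33.3, 0: exact one-third fails the strict test
  expect_equal(ev$cohort$patients_above_threshold, 1L)
  expect_equal(ev$cohort$mean_recall, mean(c(100, 100 / 3, 0)))
  expect_equal(glance(ev), ev$cohort)
  expect_equal(tidy(ev), pp)
})

test_that("cohort aggregates recompute from matched pairs", {
  sim <- small_cohort(n_patients = 2, n_days = 120, seed = 19)
  res <- run_pipeline(sim$events, sim$labels)
  pp <- res$evaluation$per_patient
  for (i in seq_len(nrow(pp))) {
    pid <- pp$patient_id[i]
    redo <- evaluate_patient(
      dplyr::filter(res$alerts, patient_id == pid),
      dplyr::filter(sim$labels, patient_id == pid),
      observed_days = pp$observed_days[i], patient_id = pid
    )
    expect_equal(redo, pp[i, ])
  }
  co <- res$evaluation$cohort
  expect_equal(co$mean_recall, mean(pp$recall))
  expect_equal(co$label_rate_pct, 100 * sum(pp$n_labels) / sum(pp$observed_days))
})

test_that("widening the soft buffer never lowers recall", {
  set.seed(60)
  lab <- mk_labels(as.Date("2021-01-01") + sort(sample(20:300, 5)))
  al <- mk_alerts(as.Date("2021-01-01") + sort(sample(0:320, 25)))
  prev <- -1
  for (b in list(c(2, 2), c(5, 4), c(10, 7), c(20, 15))) {
    ev <- evaluate_patient(al, lab, 365, buffer_before = b[1], buffer_after = b[2])
    expect_gte(ev$recall, prev)
    prev <- ev$recall
  }
})

test_that("grid search picks the dominant setting and keeps the full table", {
  g1 <- tibble::tibble(method = "robust_z", window_days = 7, threshold = 1.65)
  sim <- small_cohort(n_patients = 2, n_days = 100, seed = 23)
  f <- build_feature_series(sim$events)
  single <- grid_search(f, sim$labels, models = "mdcmp_equal", grid = g1, k = 1)
  expect_equal(nrow(single$best), 1)
  expect_equal(nrow(single$results), 1)
  grid <- dplyr::bind_rows(
    tibble::tibble(method = "robust_z", window_days = c(7, 14), threshold = 1.65),
    tibble::tibble(method = "quantile", window_days = 7, threshold = 0.95)
  )
  gs <- grid_search(f, sim$labels, models = "mdcmp_equal", grid = grid, k = 1)
  expect_equal(nrow(gs$results), 3)
  best <- gs$best
  expect_true(all(best$mean_recall >= gs$results$mean_recall - 1e-12))
  sel <- gs$results[gs$results$mean_recall == best$mean_recall, ]
  expect_true(best$mean_alerts <= min(sel$mean_alerts) + 1e-12)
})

test_that("biomarker contributions are slot frequencies over the stack", {
  V <- function(v, C = 3) matrix(v, C, C)
  mk <- function(M) cmpad:::new_cmp(M, build_contexts(11, 3, 3))
  stk <- stack_cmps(list(fA = mk(V(0.1)), fB = mk(V(0.9))))
  bio <- biomarker_contributions(stk, k_used = 0, dims = "leq_k")
  expect_equal(bio$contribution[bio$feature == "fA"], 1)
  expect_equal(bio$contribution[bio$feature == "fB"], 0)
  expect_true(bio$top_biomarker[bio$feature == "fA"])
  # k_used = F - 1: every feature contributes exactly 1/F
  bio2 <- biomarker_contributions(stk, k_used = 1, dims = "leq_k")
  expect_equal(bio2$contribution, c(0.5, 0.5))
  expect_equal(sum(bio$contribution), 1)
  expect_error(biomarker_contributions(stk, 2), class = "cmpad_input_error")
})

test_that("cohort biomarker ranking is permutation invariant", {
  r1 <- tibble::tibble(patient_id = "A", feature = c("x", "y"),
                       contribution = c(0.7, 0.3), top_biomarker = c(TRUE, FALSE))
  r2 <- tibble::tibble(patient_id = "B", feature = c("x", "y"),
                       contribution = c(0.4, 0.6), top_biomarker = c(FALSE, TRUE))
  a <- cohort_biomarkers(list(r1, r2))
  b <- cohort_biomarkers(list(r2, r1))
  expect_equal(a, b)
  expect_equal(a$median_contribution[a$feature == "x"], 0.55)
  one <- cohort_biomarkers(list(r1))
  expect_equal(one$median_contribution, c(0.7, 0.3))
})
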