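test_that("context scores average finite past cells only", {
  L <- matrix(Inf, 3, 3)
  L[3, 1] <- 0.2; L[3, 2] <- 0.4
  expect_equal(context_score_equal(L, 3), 0.3)
  expect_true(is.na(context_score_equal(L, 1)))
  L2 <- matrix(0.7, 4, 4)
  expect_equal(context_score_equal(L2, 4), 0.7)
  # random layer vs direct loop
  set.seed(14)
  R <- matrix(runif(64), 8, 8)
  for (i in 2:8) {
    expect_equal(context_score_equal(R, i), mean(R[i, 1:(i - 1)]))
  }
})

test_that("distance weighting discounts by hop count", {
  # three past contexts at hops 3, 2, 1 with distances 0.6, 0.6, 0.0
  L <- matrix(0, 4, 4)
  L[4, 1:3] <- c(0.6, 0.6, 0)
  expect_equal(context_score_distance_weighted(L, 4), 0.5 / (11 / 6))
  # constant distances are unaffected by the weighting
  L2 <- matrix(0.3, 5, 5)
  expect_equal(context_score_distance_weighted(L2, 5), 0.3)
  # single past context: its value regardless of hop
  L3 <- matrix(Inf, 4, 4); L3[4, 1] <- 0.9
  expect_equal(context_score_distance_weighted(L3, 4), 0.9)
})

test_that("univariate fusion implements the named statistics", {
  mk <- function(s) tibble::tibble(context_id = 1:3, end_date = as.Date("2021-01-01") + 1:3,
                                   score = s)
  pf <- list(a = mk(c(1, 1, 1)), b = mk(c(2, 2, 2)), c = mk(c(3, 3, 3)))
  expect_equal(fuse_univariate(pf, "sum")$score, rep(6, 3))
  expect_equal(fuse_univariate(pf, "mean")$score, rep(2, 3))
  expect_equal(fuse_univariate(pf, "median")$score, rep(2, 3))
  expect_equal(fuse_univariate(pf, "max")$score, rep(3, 3))
  # sum = F * mean exactly
  expect_equal(fuse_univariate(pf, "sum")$score, 3 * fuse_univariate(pf, "mean")$score)
  # entropy weighting is a weighted sum
  pf2 <- list(a = mk(rep(0.3, 3)), b = mk(rep(0.9, 3)))
  w <- c(a = 2 / 3, b = 1 / 3)
  expect_equal(fuse_univariate(pf2, "apen", weights = w)$score, rep(0.5, 3))
  expect_error(fuse_univariate(pf2, "apen"), class = "cmpad_input_error")
  # single feature: every method returns that feature's scores
  one <- list(a = mk(c(0.1, 0.2, 0.3)))
  for (mth in c("sum", "mean", "median", "max")) {
    expect_equal(fuse_univariate(one, mth)$score, c(0.1, 0.2, 0.3))
  }
  bad <- list(a = mk(1:3), b = mk(1:3)[1:2, ])
  expect_error(fuse_univariate(bad, "sum"), class = "cmpad_input_error")
})

# a small deterministic multi-feature table for pipeline-level scoring tests
toy_features <- function(n = 36, seed = 31) {
  set.seed(seed)
  d <- seq(as.Date("2021-01-01"), by = "day", length.out = n)
  f <- tibble::tibble(date = d)
  for (fn in cmpad_features()) f[[fn]] <- runif(n, 0, 4)
  f$missing <- FALSE
  f
}

test_that("the mdcmp route composes stack, layer and context scoring", {
  f <- toy_features()
  sc <- score_pipeline(f, model = "mdcmp_equal", k = 1)
  stk <- patient_stack(f)
  layer <- select_layer(kdim_cmp(stk), 1)
  by_hand <- vapply(seq_len(nrow(layer$values)),
                    function(i) context_score_equal(layer$values, i), numeric(1))
  expect_equal(sc$score, by_hand[!is.na(by_hand)])
  expect_equal(sc$end_date, layer$contexts$end_date[!is.na(by_hand)])
  expect_true(all(sc$k_used == 1))
  # distance-weighted variant composes the other scorer
  scd <- score_pipeline(f, model = "mdcmp_distance", k = 0)
  by_hand_d <- vapply(seq_len(nrow(layer$values)), function(i) {
    context_score_distance_weighted(select_layer(kdim_cmp(stk), 0)$values, i)
  }, numeric(1))
  expect_equal(scd$score, by_hand_d[!is.na(by_hand_d)])
})

test_that("mdcmp scores grow with k on a fixed stack", {
  f <- toy_features(seed = 32)
  prev <- NULL
  for (k in c(0, 3, 10)) {
    sc <- score_pipeline(f, model = "mdcmp_equal", k = k)
    if (!is.null(prev)) expect_true(all(sc$score >= prev - 1e-12))
    prev <- sc$score
  }
})

test_that("scores are invariant to positive affine transforms of a feature", {
  f <- toy_features(seed = 33)
  sc <- score_pipeline(f, model = "mdcmp_equal", k = 1)
  f2 <- f
  f2$bathroom_em <- 5 * f2$bathroom_em + 11
  sc2 <- score_pipeline(f2, model = "mdcmp_equal", k = 1)
  expect_equal(sc$score, sc2$score, tolerance = 1e-9)
  scs <- score_pipeline(f, model = "sum")
  scs2 <- score_pipeline(f2, model = "sum")
  expect_equal(scs$score, scs2$score, tolerance = 1e-9)
})

test_that("constant features yield flat minimal scores", {
  f <- toy_features()
  for (fn in cmpad_features()) f[[fn]] <- 2
  sc <- score_pipeline(f, model = "mdcmp_equal", k = 1)
  expect_true(all(sc$score == 0))
})

test_that("an injected UTI episode attains the top score near its onset", {
  cfg <- synth_config(n_patients = 1, n_days = 180, seed = 17,
                      uti_episodes_per_patient = 1,
                      hosp_episodes_per_patient = 0)
  sim <- simulate_patient(cfg, 0)
  f <- build_feature_series(sim$events, start_date = cfg$start_date,
                            end_date = cfg$start_date + cfg$n_days - 1)
  sc <- score_pipeline(f, model = "mdcmp_equal", k = 1)
  ep <- sim$episodes
  # at least one episode context tops its own trailing 7-day window
  ep_sc <- sc[sc$end_date >= ep$date & sc$end_date <= ep$date + ep$duration + 4, ]
  tops <- vapply(seq_len(nrow(ep_sc)), function(i) {
    ep_sc$score[i] >= max(window_scores(sc, ep_sc$end_date[i], 7))
  }, logical(1))
  expect_true(any(tops))
})

test_that("k = auto picks a valid layer and tags the output", {
  f <- toy_features(seed = 35)
  sc <- score_pipeline(f, model = "mdcmp_equal", k = "auto")
  expect_true(all(sc$k_used >= 0 & sc$k_used < 11))
  expect_equal(unique(sc$model), "mdcmp_equal")
})
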