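test_that("consecutive same-sensor firings collapse into runs", {
  ev <- mk_events(c(10, 11, 12, 7 * 60, 7 * 60 + 30, 8 * 60) * 60,
                  c("bathroom", "bathroom", "bathroom", "kitchen", "kitchen",
                    "bathroom"))
  runs <- collapse_runs(ev)
  expect_equal(runs$location, c("bathroom", "kitchen", "bathroom"))
  expect_equal(runs$n_firings, c(3L, 2L, 1L))
  expect_equal(format(runs$first_firing, "%H:%M"), c("00:10", "07:00", "08:00"))
  expect_equal(format(runs$last_firing, "%H:%M"), c("00:12", "07:30", "08:00"))
})

test_that("run collapsing is idempotent and keeps alternating events intact", {
  ev <- mk_events((1:6) * 600, rep(c("bathroom", "kitchen"), 3))
  runs <- collapse_runs(ev)
  expect_equal(nrow(runs), 6)
  again <- collapse_runs(tibble::tibble(timestamp = runs$first_firing,
                                        location = runs$location))
  expect_equal(again$location, runs$location)
  expect_equal(again$first_firing, runs$first_firing)
  one <- collapse_runs(mk_events(100, "lounge"))
  expect_equal(one$first_firing, one$last_firing)
})

test_that("unknown locations are dropped with a warning", {
  ev <- mk_events(c(60, 120), c("bathroom", "garage"))
  expect_warning(runs <- collapse_runs(ev), "garage")
  expect_equal(nrow(runs), 1)
})

test_that("dwell minutes follow the gap rule and split across midnight", {
  ev <- mk_events(c(12, 7 * 60) * 60, c("bathroom", "kitchen"))
  dur <- location_durations(collapse_runs(ev))
  expect_equal(dur$minutes[dur$location == "bathroom"], 408)  # 07:00 - 00:12
  # run ending 23:50 followed by 00:20 next day: 10 min day 1, 20 min day 2
  ev2 <- mk_events(c(23 * 3600 + 50 * 60, 24 * 3600 + 20 * 60),
                   c("lounge", "bedroom"))
  dur2 <- location_durations(collapse_runs(ev2))
  expect_equal(dur2$minutes[dur2$date == as.Date("2021-01-01")], 10)
  expect_equal(dur2$minutes[dur2$date == as.Date("2021-01-02")], 20)
  # single run: no successor, no dwell
  expect_equal(nrow(location_durations(collapse_runs(mk_events(60, "lounge")))), 0)
  # out-of-order runs are a hard error
  runs_bad <- collapse_runs(ev)
  runs_bad$first_firing <- rev(runs_bad$first_firing)
  runs_bad$last_firing <- rev(runs_bad$last_firing)
  expect_error(location_durations(runs_bad), class = "cmpad_input_error")
})

test_that("daily dwell never exceeds a day across locations", {
  set.seed(42)
  t <- sort(runif(300, 0, 5 * 86400))
  ev <- mk_events(t, sample(cmpad_locations(), 300, replace = TRUE))
  dur <- location_durations(collapse_runs(ev))
  daily <- tapply(dur$minutes, dur$date, sum)
  expect_true(all(daily <= 1440 + 1e-9))
})

test_that("early-morning and late-evening windows are half-open and day-shifted", {
  # hallway events separate the bathroom firings into distinct runs at
  # 00:10, 05:59 and 06:00
  ev <- mk_events(c(10 * 60, 2 * 3600, 5 * 3600 + 59 * 60, 5 * 3600 + 59 * 60 + 30,
                    6 * 3600, 23 * 3600 + 30 * 60),
                  c("bathroom", "hallway", "bathroom", "hallway",
                    "bathroom", "bedroom"))
  cnt <- daily_counts(collapse_runs(ev))
  d1 <- as.Date("2021-01-01")
  expect_equal(cnt$em[cnt$location == "bathroom" & cnt$date == d1], 2)
  # bedroom run at 23:30 on day d-1 counts toward day d's late-evening
  expect_equal(cnt$le[cnt$location == "bedroom" & cnt$date == d1 + 1], 1)
  expect_equal(cnt$le[cnt$location == "bedroom" & cnt$date == d1], 0)
})

test_that("raw firing counts remain available behind the visits default", {
  ev <- mk_events(c(10, 11, 12) * 60, rep("bathroom", 3))
  runs <- collapse_runs(ev)
  d1 <- as.Date("2021-01-01")
  cnt <- daily_counts(runs)
  expect_equal(cnt$count[cnt$date == d1], 1)
  raw <- daily_counts(runs, counts = "raw")
  expect_equal(raw$count[raw$date == d1], 3)
})

test_that("hourly histograms normalize and fall back to uniform", {
  ev <- mk_events(c(2 * 3600 + c(1, 2, 3) * 60), rep("kitchen", 3))
  runs <- collapse_runs(ev)
  h <- hourly_histogram(runs, as.Date("2021-01-01"), "kitchen")
  expect_equal(h[3], 1)
  expect_equal(sum(h), 1)
  expect_equal(hourly_histogram(runs, as.Date("2021-01-01"), "lounge"),
               rep(1 / 24, 24))
  ev2 <- mk_events(c(30, 6 * 3600, 12 * 3600), c("lounge", "kitchen", "lounge"))
  h2 <- hourly_histogram(collapse_runs(ev2), as.Date("2021-01-01"), "lounge")
  expect_equal(h2[c(1, 13)], c(0.5, 0.5))
})

test_that("1D Wasserstein matches closed forms and is a metric", {
  p <- rep(0, 24); p[3] <- 1
  q <- rep(0, 24); q[6] <- 1
  expect_equal(wasserstein_1d(p, p), 0)
  expect_equal(wasserstein_1d(p, q), 3)
  p2 <- c(1, rep(0, 23)); q2 <- c(0.5, 0.5, rep(0, 22))
  expect_equal(wasserstein_1d(p2, q2), 0.5)
  expect_error(wasserstein_1d(p, q * 2), class = "cmpad_input_error")
  set.seed(1)
  for (i in 1:25) {
    a <- as.vector(rmultinom(1, 40, rep(1, 24))) / 40
    b <- as.vector(rmultinom(1, 40, rep(1, 24))) / 40
    cc <- as.vector(rmultinom(1, 40, rep(1, 24))) / 40
    expect_gte(wasserstein_1d(a, b), 0)
    expect_equal(wasserstein_1d(a, b), wasserstein_1d(b, a))
    expect_lte(wasserstein_1d(a, cc),
               wasserstein_1d(a, b) + wasserstein_1d(b, cc) + 1e-12)
  }
})

test_that("the daily feature matrix has the 11-feature contract", {
  # identical activity every day: all Wasserstein features 0 from day 2
  times <- unlist(lapply(0:9, function(d) d * 86400 + c(8, 12, 20) * 3600))
  ev <- mk_events(times, rep(c("bathroom", "kitchen", "lounge"), 10))
  f <- build_feature_series(ev)
  expect_equal(nrow(f), 10)
  expect_true(all(cmpad_features() %in% names(f)))
  expect_equal(f$bathroom_wass, rep(0, 10))
  expect_equal(f$lounge_wass, rep(0, 10))
  expect_true(all(as.matrix(f[cmpad_features()]) >= 0))
  expect_true(all(is.finite(as.matrix(f[cmpad_features()]))))
  expect_error(build_feature_series(ev[0, ]), class = "cmpad_input_error")
})

test_that("empty calendar days are zero-filled and masked", {
  times <- c(8 * 3600, 2 * 86400 + 8 * 3600)  # day 2 has no events
  ev <- mk_events(times, c("bathroom", "kitchen"))
  f <- build_feature_series(ev)
  expect_equal(f$missing, c(FALSE, TRUE, FALSE))
  expect_equal(unlist(f[2, cmpad_features()]), setNames(rep(0, 11), cmpad_features()))
})

test_that("features from a simulated UTI patient show elevated night bathroom use", {
  cfg <- synth_config(n_patients = 1, n_days = 120, seed = 13,
                      uti_episodes_per_patient = 2,
                      hosp_episodes_per_patient = 0)
  sim <- simulate_patient(cfg, 0)
  f <- build_feature_series(sim$events, start_date = cfg$start_date,
                            end_date = cfg$start_date + cfg$n_days - 1)
  ep_days <- unlist(lapply(seq_len(nrow(sim$episodes)), function(e) {
    as.character(seq(sim$episodes$date[e], by = "day",
                     length.out = sim$episodes$duration[e]))
  }))
  inside <- f$bathroom_em[as.character(f$date) %in% ep_days]
  outside <- f$bathroom_em[!as.character(f$date) %in% ep_days]
  expect_gt(mean(inside), 2 * mean(outside))
})
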