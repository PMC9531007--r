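#' Collapse consecutive same-sensor firings into visit runs
#'
#' PIR sensors chatter: a single visit to a room produces a burst of
#' consecutive firings. Consecutive firings from the same sensor are
#' collapsed into one run, keeping the first and last firing time and the
#' number of firings. Records with a location outside the five-room
#' vocabulary are dropped with a warning.
#'
#' @param events Tibble with `timestamp` (POSIXct, sorted) and `location`
#'   columns; a `patient_id` column, if present, is ignored (collapse one
#'   patient at a time).
#'
#' @return Tibble of runs: `location`, `first_firing`, `last_firing`,
#'   `n_firings`. Consecutive runs differ in location.
#' @export
collapse_runs <- function(events) {
  stopifnot(all(c("timestamp", "location") %in% names(events)))
  bad <- !events$location %in% .cmpad_locations
  if (any(bad)) {
    warn(paste0("dropping ", sum(bad), " event(s) with unknown location: ",
                paste(unique(events$location[bad]), collapse = ", ")))
    events <- events[!bad, , drop = FALSE]
  }
  if (nrow(events) == 0) {
    return(tibble::tibble(location = character(),
                          first_firing = as.POSIXct(character(), tz = "UTC"),
                          last_firing = as.POSIXct(character(), tz = "UTC"),
                          n_firings = integer()))
  }
  if (is.unsorted(events$timestamp)) {
    abort("events must be sorted by timestamp", class = "cmpad_input_error")
  }
  r <- rle(events$location)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble::tibble(
    location = r$values,
    first_firing = events$timestamp[starts],
    last_firing = events$timestamp[ends],
    n_firings = r$lengths
  )
}

#' Daily dwell minutes per location
#'
#' The time attributed to a run's location is the gap from that run's last
#' firing to the next run's first firing (the person is assumed to stay in
#' the room until the next sensor fires elsewhere). The final run contributes
#' no dwell. Gaps spanning midnight are split into their respective calendar
#' days; per-day totals are capped at 1440 minutes.
#'
#' @param runs Run tibble from [collapse_runs()], time-ordered.
#' @param rule `"gap"` (default; next run's first firing minus this run's
#'   last firing) or `"span"` (next first minus this first), the common PIR
#'   alternative.
#'
#' @return Tibble `date`, `location`, `minutes`.
#' @export
location_durations <- function(runs, rule = c("gap", "span")) {
  rule <- match.arg(rule)
  if (nrow(runs) < 2) {
    return(tibble::tibble(date = as.Date(character()), location = character(),
                          minutes = numeric()))
  }
  k <- seq_len(nrow(runs) - 1L)
  s <- if (rule == "gap") runs$last_firing[k] else runs$first_firing[k]
  e <- runs$first_firing[k + 1L]
  if (any(as.numeric(e) < as.numeric(s))) {
    abort("negative dwell: runs are out of order", class = "cmpad_input_error")
  }
  loc <- runs$location[k]
  ds <- as.Date(s, tz = "UTC")
  de <- as.Date(e, tz = "UTC")
  same <- ds == de
  parts <- list(tibble::tibble(date = ds[same], location = loc[same],
                               minutes = as.numeric(e[same] - s[same], units = "mins")))
  if (any(!same)) {
    # split cross-midnight gaps day by day (rare: gaps > a few hours)
    idx <- which(!same)
    cross <- purrr::map(idx, function(i) {
      days <- seq(ds[i], de[i], by = "day")
      day0 <- as.POSIXct(as.numeric(as.Date(days)) * 86400,
                         origin = "1970-01-01", tz = "UTC")
      lo <- pmax(as.numeric(day0), as.numeric(s[i]))
      hi <- pmin(as.numeric(day0) + 86400, as.numeric(e[i]))
      tibble::tibble(date = days, location = loc[i],
                     minutes = pmax(hi - lo, 0) / 60)
    })
    parts <- c(parts, cross)
  }
  dplyr::bind_rows(parts) |>
    dplyr::group_by(.data$date, .data$location) |>
    dplyr::summarise(minutes = min(sum(.data$minutes), 1440), .groups = "drop") |>
    dplyr::arrange(.data$date, .data$location)
}

#' Daily visit counts with early-morning and late-evening windows
#'
#' Counts runs (visits) per day and location by the run's first firing, plus
#' early-morning counts (first firing in the half-open window
#' \[00:00, 06:00) of the current day) and late-evening counts (first firing
#' in \[18:00, 24:00) of the *previous* day, attributed to the current day)
#' for bathroom, kitchen and bedroom.
#'
#' @param runs Run tibble from [collapse_runs()].
#' @param counts `"visits"` (default: one unit per run, so burst length --
#'   hardware chatter -- does not masquerade as activity) or `"raw"` (sum of
#'   sensor firings in the run).
#'
#' @return Tibble keyed by `date` and `location` with `count`, `em`
#'   (early-morning) and `le` (late-evening) columns. `le` on the first
#'   observed day is 0 (no previous day).
#' @export
daily_counts <- function(runs, counts = c("visits", "raw")) {
  counts <- match.arg(counts)
  if (nrow(runs) == 0) {
    return(tibble::tibble(date = as.Date(character()), location = character(),
                          count = numeric(), em = numeric(), le = numeric()))
  }
  w <- if (counts == "raw") as.numeric(runs$n_firings) else rep(1, nrow(runs))
  hr <- as.integer(format(runs$first_firing, "%H", tz = "UTC"))
  date <- as.Date(runs$first_firing, tz = "UTC")
  base <- tibble::tibble(date = date, location = runs$location, w = w, hr = hr)
  tot <- base |>
    dplyr::group_by(.data$date, .data$location) |>
    dplyr::summarise(count = sum(.data$w),
                     em = sum(.data$w[.data$hr < 6]),
                     le_prev = sum(.data$w[.data$hr >= 18]),
                     .groups = "drop")
  # late-evening of day d-1 becomes the le value of day d
  le <- dplyr::transmute(tot, date = .data$date + 1, location = .data$location,
                         le = .data$le_prev)
  dplyr::full_join(dplyr::select(tot, -"le_prev"), le,
                   by = c("date", "location")) |>
    dplyr::mutate(dplyr::across(c("count", "em", "le"), ~ tidyr::replace_na(.x, 0))) |>
    dplyr::arrange(.data$date, .data$location)
}

#' Hourly activity histogram for one location-day
#'
#' 24-bin probability vector of run start times (bins are the half-open
#' wall-clock hours \[h, h+1)). A day with no activity at the location maps
#' to the uniform vector, so the day-to-day Wasserstein change is defined
#' everywhere and a dead day reads as maximally spread activity.
#'
#' @param runs Run tibble from [collapse_runs()].
#' @param day A `Date`.
#' @param location One of [cmpad_locations()].
#'
#' @return Numeric vector of length 24 summing to 1.
#' @export
hourly_histogram <- function(runs, day, location) {
  sel <- runs$location == location &
    as.Date(runs$first_firing, tz = "UTC") == as.Date(day)
  if (!any(sel)) return(rep(1 / 24, 24))
  hr <- as.integer(format(runs$first_firing[sel], "%H", tz = "UTC"))
  tab <- tabulate(hr + 1L, nbins = 24)
  tab / sum(tab)
}

#' First-order Wasserstein distance between two hourly histograms
#'
#' Earth-mover distance on the line with unit ground distance between
#' adjacent hour bins: the sum of absolute differences of the two CDFs.
#'
#' @param p,q Length-24 probability vectors (each summing to 1 within 1e-9).
#'
#' @return Non-negative distance; `abs(h1 - h2)` for point masses at hours
#'   h1 and h2.
#' @export
wasserstein_1d <- function(p, q) {
  stopifnot(length(p) == length(q))
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    abort("histograms must sum to 1", class = "cmpad_input_error")
  }
  sum(abs(cumsum(p - q)))
}

# per-location day x 24 histogram matrix over a contiguous day grid;
# zero-activity rows become uniform
.hour_hist_matrix <- function(runs, days, location) {
  m <- matrix(0, nrow = length(days), ncol = 24)
  sel <- runs$location == location
  if (any(sel)) {
    d <- as.Date(runs$first_firing[sel], tz = "UTC")
    hr <- as.integer(format(runs$first_firing[sel], "%H", tz = "UTC"))
    di <- match(d, days)
    keep <- !is.na(di)
    for (i in which(keep)) m[di[i], hr[i] + 1L] <- m[di[i], hr[i] + 1L] + 1
  }
  rs <- rowSums(m)
  m[rs == 0, ] <- 1 / 24
  m / rowSums(m)
}

#' Build the daily 11-feature series for each patient
#'
#' Turns a raw event stream into the per-patient, calendar-contiguous daily
#' feature matrix used by the anomaly pipeline: Wasserstein day-to-day change
#' of the hourly activity histogram (bathroom, hallway, lounge),
#' early-morning and late-evening visit counts (bathroom, kitchen, bedroom),
#' and daily dwell minutes (bedroom, bathroom). Wasserstein features for day
#' d compare day d-1 with day d; the first day's Wasserstein features are 0.
#' Days with no events at all are zero-filled and flagged in `missing`.
#'
#' @param events Event tibble (`patient_id` optional, `timestamp`,
#'   `location`); may contain several patients.
#' @param start_date,end_date Optional span override (Dates); defaults to
#'   each patient's observed span.
#' @param counts Passed to [daily_counts()].
#' @param duration_rule Passed to [location_durations()] (`rule`).
#'
#' @return Tibble with `patient_id`, `date`, the 11 [cmpad_features()]
#'   columns, and `missing` (logical).
#' @export
build_feature_series <- function(events, start_date = NULL, end_date = NULL,
                                 counts = c("visits", "raw"),
                                 duration_rule = c("gap", "span")) {
  counts <- match.arg(counts)
  duration_rule <- match.arg(duration_rule)
  if (!"patient_id" %in% names(events)) {
    events <- dplyr::mutate(events, patient_id = "P001")
  }
  if (nrow(events) == 0) abort("empty event stream", class = "cmpad_input_error")
  events |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(~ .feature_series_one(.x, start_date, end_date,
                                              counts, duration_rule)) |>
    dplyr::ungroup()
}

.feature_series_one <- function(events, start_date, end_date, counts, duration_rule) {
  runs <- collapse_runs(events)
  if (nrow(runs) == 0) abort("empty event stream", class = "cmpad_input_error")
  obs_dates <- as.Date(runs$first_firing, tz = "UTC")
  d0 <- if (is.null(start_date)) min(obs_dates) else as.Date(start_date)
  d1 <- if (is.null(end_date)) max(obs_dates) else as.Date(end_date)
  if (d1 < d0 + 1) abort("stream must span at least 2 days", class = "cmpad_input_error")
  days <- seq(d0, d1, by = "day")
  n <- length(days)

  cnt <- daily_counts(runs, counts = counts)
  dur <- location_durations(runs, rule = duration_rule)

  pick <- function(tbl, loc, col) {
    v <- numeric(n)
    sel <- tbl$location == loc
    i <- match(tbl$date[sel], days)
    keep <- !is.na(i)
    v[i[keep]] <- tbl[[col]][sel][keep]
    v
  }

  wass <- function(loc) {
    h <- .hour_hist_matrix(runs, days, loc)
    dcdf <- apply(h, 1, cumsum)            # 24 x n
    w <- c(0, colSums(abs(dcdf[, -1, drop = FALSE] - dcdf[, -n, drop = FALSE])))
    w
  }

  out <- tibble::tibble(
    date = days,
    bathroom_wass = wass("bathroom"),
    hallway_wass = wass("hallway"),
    lounge_wass = wass("lounge"),
    bathroom_em = pick(cnt, "bathroom", "em"),
    bathroom_le = pick(cnt, "bathroom", "le"),
    kitchen_em = pick(cnt, "kitchen", "em"),
    kitchen_le = pick(cnt, "kitchen", "le"),
    bedroom_em = pick(cnt, "bedroom", "em"),
    bedroom_le = pick(cnt, "bedroom", "le"),
    bedroom_duration = pick(dur, "bedroom", "minutes"),
    bathroom_duration = pick(dur, "bathroom", "minutes")
  )
  miss <- !days %in% obs_dates
  out[miss, .cmpad_features] <- 0
  out$missing <- miss
  out
}
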