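#' Default hourly visit-rate profiles
#'
#' Base Poisson visit rates (visits/hour) for each location and hour of day,
#' encoding plausible circadian structure: bathroom use is bimodal
#' (morning/evening) with a low overnight rate, bedroom activity is
#' night-loaded, kitchen activity peaks at meal times, lounge activity is
#' concentrated in the daytime, and hallway traffic is roughly flat through
#' waking hours.
#'
#' @return A 5 x 24 numeric matrix; rows named by location, columns by hour
#'   (0-23).
#' @export
default_hourly_profiles <- function() {
  h <- 0:23
  # night-time floors are kept well above zero: nocturnal restlessness and
  # toilet visits are characteristic of this population, and every engineered
  # count window needs a non-degenerate baseline for shape-based distances
  bathroom <- rep(0.15, 24)
  bathroom[h %in% 0:5] <- 0.3
  bathroom[h %in% 7:9] <- 0.7
  bathroom[h %in% 20:23] <- 0.5
  bedroom <- rep(0.1, 24)
  bedroom[h %in% c(21, 22, 23)] <- 0.8
  bedroom[h %in% 0:6] <- 0.5
  kitchen <- rep(0.15, 24)
  kitchen[h %in% 0:5] <- 0.25
  kitchen[h %in% 7:8] <- 1.1
  kitchen[h %in% 12:13] <- 0.9
  kitchen[h %in% 18:20] <- 1.0
  lounge <- rep(0.05, 24)
  lounge[h %in% 9:21] <- 0.55
  hallway <- rep(0.1, 24)
  hallway[h %in% 7:22] <- 0.35
  out <- rbind(bathroom = bathroom, bedroom = bedroom, kitchen = kitchen,
               lounge = lounge, hallway = hallway)
  colnames(out) <- sprintf("h%02d", h)
  out
}

#' Synthetic cohort configuration
#'
#' Parameters of the seeded household-movement simulator. Per day, location
#' and hour the simulator draws a Poisson number of visits at rate
#' `lambda(loc, hour) * day_noise * episode_multiplier`; each visit is
#' expanded into `1 + Poisson(burst_size_mean)` consecutive sensor firings at
#' one-minute spacing. Two episode types are injected with ground-truth
#' labels at the episode start date: UTI-like episodes multiply night-time
#' (00:00-06:00) bathroom rates by `uti_night_bathroom_multiplier` and night
#' bedroom rates by `uti_night_bedroom_multiplier` for 3-8 days (a UTI
#' typically takes 3 to 8 days to present); hospitalization-like episodes
#' scale all activity by `hosp_activity_multiplier`.
#'
#' @param n_patients Number of patients in the cohort.
#' @param n_days Days of observation per patient (default 624, the study-scale
#'   average patient journey).
#' @param start_date First observation day.
#' @param hourly_rate_profile 5 x 24 matrix of base visit rates, rows named by
#'   location (see [default_hourly_profiles()]).
#' @param day_noise_sigma Lognormal sigma of the per-day multiplicative noise
#'   shared across locations (unit mean).
#' @param burst_size_mean Mean number of extra consecutive firings per visit.
#' @param uti_episodes_per_patient,hosp_episodes_per_patient Episodes injected
#'   per patient.
#' @param uti_duration_days,hosp_duration_days Integer range (length 2) of
#'   episode durations in days.
#' @param uti_night_bathroom_multiplier,uti_night_bedroom_multiplier,hosp_activity_multiplier
#'   Rate multipliers (> 0) applied during episodes.
#' @param min_gap_days Minimum clean days between injected episodes so that
#'   thresholding baselines can re-establish.
#' @param seed Integer seed; all simulator randomness derives from it.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_patients = 15,
                         n_days = 624,
                         start_date = as.Date("2020-01-01"),
                         hourly_rate_profile = default_hourly_profiles(),
                         day_noise_sigma = 0.25,
                         burst_size_mean = 2,
                         uti_episodes_per_patient = 2,
                         uti_duration_days = c(3L, 8L),
                         uti_night_bathroom_multiplier = 3,
                         uti_night_bedroom_multiplier = 1.5,
                         hosp_episodes_per_patient = 1,
                         hosp_duration_days = c(2L, 10L),
                         hosp_activity_multiplier = 0.1,
                         min_gap_days = 14,
                         seed = 1L) {
  stopifnot(
    n_patients >= 0, n_days >= 1,
    is.matrix(hourly_rate_profile), ncol(hourly_rate_profile) == 24,
    all(.cmpad_locations %in% rownames(hourly_rate_profile)),
    all(hourly_rate_profile >= 0),
    day_noise_sigma >= 0, burst_size_mean >= 0,
    uti_night_bathroom_multiplier > 0, uti_night_bedroom_multiplier > 0,
    hosp_activity_multiplier > 0,
    length(uti_duration_days) == 2, length(hosp_duration_days) == 2,
    uti_duration_days[1] >= 1, uti_duration_days[1] <= uti_duration_days[2],
    hosp_duration_days[1] >= 1, hosp_duration_days[1] <= hosp_duration_days[2]
  )
  cfg <- list(
    n_patients = as.integer(n_patients), n_days = as.integer(n_days),
    start_date = as.Date(start_date),
    hourly_rate_profile = hourly_rate_profile[.cmpad_locations, , drop = FALSE],
    day_noise_sigma = day_noise_sigma, burst_size_mean = burst_size_mean,
    uti_episodes_per_patient = as.integer(uti_episodes_per_patient),
    uti_duration_days = as.integer(uti_duration_days),
    uti_night_bathroom_multiplier = uti_night_bathroom_multiplier,
    uti_night_bedroom_multiplier = uti_night_bedroom_multiplier,
    hosp_episodes_per_patient = as.integer(hosp_episodes_per_patient),
    hosp_duration_days = as.integer(hosp_duration_days),
    hosp_activity_multiplier = hosp_activity_multiplier,
    min_gap_days = as.integer(min_gap_days),
    seed = as.integer(seed)
  )
  structure(cfg, class = "synth_config")
}

# deterministic per-patient stream seed, kept below 2^31
.patient_seed <- function(seed, patient_index) {
  as.integer((as.numeric(seed) * 7919 + (patient_index + 1) * 104729) %% 2147483647)
}

# place episodes (type, start, duration) uniformly at random subject to
# min_gap_days separation between episode intervals; rejection sampling
.place_episodes <- function(cfg) {
  want <- c(rep("UTI", cfg$uti_episodes_per_patient),
            rep("hospitalization", cfg$hosp_episodes_per_patient))
  if (length(want) == 0) {
    return(tibble::tibble(type = character(), start = integer(), duration = integer()))
  }
  placed <- NULL
  for (type in want) {
    rng <- if (type == "UTI") cfg$uti_duration_days else cfg$hosp_duration_days
    ok <- FALSE
    for (try in seq_len(2000L)) {
      dur <- sample(rng[1]:rng[2], 1L)
      # leave a clean baseline run-in before the first possible episode, for
      # the same reason episodes are separated: thresholds need history
      lo <- cfg$min_gap_days
      if (cfg$n_days - dur < lo) break
      start <- sample(lo:(cfg$n_days - dur), 1L)
      clash <- FALSE
      if (!is.null(placed)) {
        clash <- any(start <= placed$start + placed$duration - 1 + cfg$min_gap_days &
                       placed$start <= start + dur - 1 + cfg$min_gap_days)
      }
      if (!clash) {
        placed <- dplyr::bind_rows(placed, tibble::tibble(type = type, start = start,
                                                          duration = dur))
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(paste0("n_days = ", cfg$n_days, " is too small to place ",
                   length(want), " episodes with a ", cfg$min_gap_days,
                   "-day gap between them"),
            class = "cmpad_config_error")
    }
  }
  dplyr::arrange(placed, .data$start)
}

#' Simulate one patient's sensor event stream
#'
#' Generates a seeded PIR event stream plus ground-truth episode labels for a
#' single synthetic patient. Output is fully determined by
#' `(cfg$seed, patient_index)`.
#'
#' @param cfg A [synth_config()].
#' @param patient_index Zero-based patient index, `< cfg$n_patients`.
#'
#' @return A list with `events` (tibble: `patient_id`, `timestamp` POSIXct
#'   UTC at minute resolution, `location`) and `labels` (tibble:
#'   `patient_id`, `date`, `type`), plus an `episodes` tibble recording the
#'   injected ground truth (start date and duration).
#' @export
simulate_patient <- function(cfg, patient_index) {
  stopifnot(inherits(cfg, "synth_config"),
            patient_index >= 0, patient_index < cfg$n_patients)
  pid <- sprintf("P%03d", patient_index + 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(.patient_seed(cfg$seed, patient_index))

  episodes <- .place_episodes(cfg)
  n_days <- cfg$n_days
  day_noise <- rlnorm(n_days, meanlog = -cfg$day_noise_sigma^2 / 2,
                      sdlog = cfg$day_noise_sigma)

  # rate tensor: location x hour, modulated per day
  base <- cfg$hourly_rate_profile
  locs <- .cmpad_locations
  night <- 1:6  # columns for hours 0-5

  ev_list <- vector("list", n_days)
  for (d in seq_len(n_days) - 1L) {
    lam <- base * day_noise[d + 1]
    if (nrow(episodes)) {
      for (e in seq_len(nrow(episodes))) {
        if (d >= episodes$start[e] && d < episodes$start[e] + episodes$duration[e]) {
          if (episodes$type[e] == "UTI") {
            lam["bathroom", night] <- lam["bathroom", night] * cfg$uti_night_bathroom_multiplier
            lam["bedroom", night] <- lam["bedroom", night] * cfg$uti_night_bedroom_multiplier
          } else {
            lam <- lam * cfg$hosp_activity_multiplier
          }
        }
      }
    }
    n_visits <- matrix(rpois(length(lam), lam), nrow = nrow(lam))
    if (sum(n_visits) == 0) next
    idx <- which(n_visits > 0, arr.ind = TRUE)
    loc <- rep(locs[idx[, 1]], n_visits[n_visits > 0])
    hour <- rep(idx[, 2] - 1L, n_visits[n_visits > 0])
    minute <- floor(runif(length(loc)) * 60)
    n_fir <- 1L + rpois(length(loc), cfg$burst_size_mean)
    t0 <- as.numeric(cfg$start_date) * 86400 + d * 86400 + hour * 3600 + minute * 60
    # expand each visit into consecutive one-minute-spaced firings
    times <- rep(t0, n_fir) + unlist(lapply(n_fir, function(k) 60 * (seq_len(k) - 1)))
    ev_list[[d + 1]] <- tibble::tibble(
      timestamp = times, location = rep(loc, n_fir)
    )
  }
  events <- dplyr::bind_rows(ev_list)
  if (nrow(events)) {
    events <- dplyr::arrange(events, .data$timestamp, .data$location)
    events$timestamp <- as.POSIXct(events$timestamp, origin = "1970-01-01", tz = "UTC")
  } else {
    events <- tibble::tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                             location = character())
  }
  events <- tibble::tibble(patient_id = rep(pid, nrow(events)), events)

  labels <- tibble::tibble(
    patient_id = rep(pid, nrow(episodes)),
    date = cfg$start_date + episodes$start,
    type = episodes$type
  )
  episodes <- tibble::tibble(patient_id = rep(pid, nrow(episodes)),
                             date = cfg$start_date + episodes$start,
                             type = episodes$type,
                             duration = episodes$duration)
  list(events = events, labels = labels, episodes = episodes)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a synthetic cohort
#'
#' Runs [simulate_patient()] for every patient with independently derived
#' seeds and binds the results.
#'
#' @param cfg A [synth_config()].
#' @param out_dir Optional directory; if given, writes `events.csv`
#'   (`patient_id,timestamp,location`, ISO-8601 minute timestamps) and
#'   `labels.csv` (`patient_id,date,type`).
#'
#' @return A list with cohort-level `events`, `labels` and `episodes`
#'   tibbles.
#' @export
simulate_cohort <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  sims <- purrr::map(seq_len(cfg$n_patients) - 1L, ~ simulate_patient(cfg, .x))
  out <- list(
    events = dplyr::bind_rows(purrr::map(sims, "events")),
    labels = dplyr::bind_rows(purrr::map(sims, "labels")),
    episodes = dplyr::bind_rows(purrr::map(sims, "episodes"))
  )
  if (nrow(out$events) == 0) {
    out$events <- tibble::tibble(patient_id = character(),
                                 timestamp = as.POSIXct(character(), tz = "UTC"),
                                 location = character())
  }
  if (nrow(out$labels) == 0) {
    out$labels <- tibble::tibble(patient_id = character(),
                                 date = as.Date(character()), type = character())
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ev <- dplyr::mutate(out$events,
                        timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M", tz = "UTC"))
    readr::write_csv(ev, file.path(out_dir, "events.csv"))
    readr::write_csv(out$labels, file.path(out_dir, "labels.csv"))
  }
  out
}
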