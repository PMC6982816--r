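#' Template circadian activity profile
#'
#' A smooth 1440-minute activity template on the noon-to-noon grid:
#' high and flat through the afternoon and evening, a soft evening
#' wind-down, a low overnight plateau and a morning rise. Values are
#' relative (night floor to 1); the per-patient amplitude scales them
#' into AI units. The night floor is kept well above zero — a worn but
#' resting wrist still registers postural and respiratory micro-movement,
#' which is also what separates quiet wear from the flat signal of a
#' removed device.
#'
#' @param wake,bed clock times ("HH:MM") of the morning rise and evening
#'   wind-down midpoints.
#' @param night relative activity level of the overnight plateau.
#' @param transition steepness of the rise/fall, in minutes.
#' @return A numeric vector of length 1440 (minute 0 = 12:00 noon).
#' @export
default_circadian_profile <- function(wake = "07:00", bed = "22:30",
                                      night = 0.15, transition = 40) {
  clock_min <- function(hhmm) {
    p <- as.integer(strsplit(hhmm, ":", fixed = TRUE)[[1L]])
    p[1L] * 60L + p[2L]
  }
  wk <- clock_min(wake); bd <- clock_min(bed)
  m <- 0:(MINUTES_PER_DAY - 1L)
  clock <- (m + 720L) %% MINUTES_PER_DAY
  awake <- stats::plogis((clock - wk) / transition) *
    stats::plogis((bd - clock) / transition)
  night + (1 - night) * awake
}

#' Define a synthetic patient scenario
#'
#' A scenario fixes everything needed to generate one patient's
#' monitoring period deterministically: the circadian template, the
#' per-patient activity amplitude, multiplicative minute noise, day-level
#' timing jitter, planted non-wear gaps, clinical events and pre-event
#' deterioration.
#'
#' Deterioration has two independent components, mirroring the two ways
#' patients decline: \emph{amplitude decay} multiplies the day's
#' activity by `exp(-amplitude_decay_rate * days_into_onset)` (doing
#' less), and \emph{regularity decay} warps the daily schedule by a
#' random smooth time displacement whose magnitude grows as
#' `regularity_decay_rate * days_into_onset` minutes (doing the same
#' amount at increasingly erratic times), which lowers the day-to-day
#' correlation while leaving the total roughly unchanged.
#'
#' @param patient_id identifier.
#' @param n_days number of monitored days (day indices 0 to n_days-1).
#' @param base_amplitude per-patient activity scale, in AI units at the
#'   daytime plateau.
#' @param circadian_profile 1440-vector template
#'   ([default_circadian_profile()]).
#' @param noise_sdlog sdlog of the i.i.d. multiplicative lognormal
#'   minute noise.
#' @param jitter_sd standard deviation (minutes) of the day-level
#'   schedule shift present even in stable patients.
#' @param nonwear_gaps data frame `day,start_minute,length` of planted
#'   off-wrist gaps (minutes on the noon-to-noon grid).
#' @param events data frame `day,kind` of clinical events
#'   (`"ER"`/`"RH"`/`"OPD"`).
#' @param deterioration data frame `event_day,onset_days_before,
#'   amplitude_decay_rate,regularity_decay_rate`; the decline spans the
#'   `onset_days_before` days ending the day before `event_day`.
#' @param seed RNG seed making the patient reproducible.
#' @return An object of class `"patient_scenario"`.
#' @export
patient_scenario <- function(patient_id = "p1", n_days = 60,
                             base_amplitude = 30,
                             circadian_profile = default_circadian_profile(),
                             noise_sdlog = 0.12, jitter_sd = 4,
                             nonwear_gaps = NULL, events = NULL,
                             deterioration = NULL, seed = 1L) {
  stopifnot(n_days >= 1, base_amplitude > 0,
            length(circadian_profile) == MINUTES_PER_DAY,
            all(circadian_profile > 0), noise_sdlog >= 0)
  structure(list(patient_id = as.character(patient_id),
                 n_days = as.integer(n_days),
                 base_amplitude = base_amplitude,
                 circadian_profile = circadian_profile,
                 noise_sdlog = noise_sdlog, jitter_sd = jitter_sd,
                 nonwear_gaps = nonwear_gaps, events = events,
                 deterioration = deterioration, seed = as.integer(seed)),
            class = "patient_scenario")
}

# Per-day multipliers implied by the scenario's deterioration rows:
# a list with amplitude factor and warp magnitude (minutes) per day index.
deterioration_schedule <- function(scenario) {
  nd <- scenario$n_days
  amp <- rep(1, nd)
  warp <- rep(0, nd)
  det <- scenario$deterioration
  if (!is.null(det) && nrow(det)) {
    for (r in seq_len(nrow(det))) {
      e <- det$event_day[r]
      onset <- det$onset_days_before[r]
      days <- seq(max(0L, e - onset), e - 1L)
      days <- days[days >= 0L & days < nd]
      into <- days - (e - onset) + 1L
      amp[days + 1L] <- amp[days + 1L] *
        exp(-det$amplitude_decay_rate[r] * into)
      warp[days + 1L] <- pmax(warp[days + 1L],
                              det$regularity_decay_rate[r] * into)
    }
  }
  list(amp = amp, warp = warp)
}

#' Generate a patient's minute-wise AI series
#'
#' Day d, minute m is generated as
#' `base_amplitude * amp(d) * profile[warped minute] * lognormal noise`,
#' where the warp combines a small day-level schedule shift with the
#' deterioration time-warp (see [patient_scenario()]). Planted non-wear
#' gaps become `NA` minutes with `wear = FALSE`. Fully deterministic
#' given the scenario seed.
#'
#' @param scenario a [patient_scenario()].
#' @return A list: `ai` (n_days x 1440 matrix, `NA` in gaps), `wear`
#'   (logical matrix), `scenario` (the input, as ground-truth log).
#' @export
generate_minute_ai <- function(scenario) {
  stopifnot(inherits(scenario, "patient_scenario"))
  nd <- scenario$n_days
  prof <- scenario$circadian_profile
  sched <- deterioration_schedule(scenario)
  m <- 0:(MINUTES_PER_DAY - 1L)
  with_seed(scenario$seed, {
    ai <- matrix(NA_real_, nd, MINUTES_PER_DAY)
    wear <- matrix(TRUE, nd, MINUTES_PER_DAY)
    for (d in seq_len(nd)) {
      shift <- stats::rnorm(1, 0, scenario$jitter_sd)
      wamp <- sched$warp[d]
      phase <- stats::runif(1, 0, 2 * pi)
      src <- m + shift +
        wamp * sin(2 * pi * m / MINUTES_PER_DAY + phase)
      idx <- (round(src) %% MINUTES_PER_DAY) + 1L
      noise <- exp(stats::rnorm(MINUTES_PER_DAY, 0, scenario$noise_sdlog))
      ai[d, ] <- scenario$base_amplitude * sched$amp[d] * prof[idx] * noise
    }
    gaps <- scenario$nonwear_gaps
    if (!is.null(gaps) && nrow(gaps)) {
      for (r in seq_len(nrow(gaps))) {
        d <- gaps$day[r] + 1L
        if (d < 1L || d > nd) next
        mm <- gaps$start_minute[r] + seq_len(gaps$length[r]) - 1L
        mm <- mm[mm >= 0L & mm < MINUTES_PER_DAY] + 1L
        wear[d, mm] <- FALSE
        ai[d, mm] <- NA_real_
      }
    }
    list(ai = ai, wear = wear, scenario = scenario)
  })
}

#' Day records from a generated minute-AI matrix
#'
#' @param gen output of [generate_minute_ai()].
#' @return A list of [day_record()] objects (day indices 0-based).
#' @export
scenario_day_records <- function(gen) {
  lapply(seq_len(nrow(gen$ai)), function(d) {
    day_record(gen$scenario$patient_id, d - 1L, NA,
               gen$ai[d, ], gen$wear[d, ])
  })
}

#' Render a minute-AI day as a raw 20 Hz stream
#'
#' Inverse of the activity-index computation: each worn minute is
#' rendered as zero-mean tri-axial Gaussian jitter around the gravity
#' vector with per-axis standard deviation `ai / 60`, which the default
#' AI model (noise_sd = 0, 1-second epochs) recovers up to sampling
#' error. Non-wear minutes are rendered as a constant gravity vector.
#' Sample timestamps sit at the centre of their sampling interval so
#' epoch assignment is robust to floating-point rounding.
#'
#' @param minute_ai numeric 1440-vector of target minute AIs (`NA`
#'   treated as non-wear).
#' @param wear logical 1440-vector; defaults to `!is.na(minute_ai)`.
#' @param window_start POSIXct of the day's noon start.
#' @param sample_rate sampling rate in Hz.
#' @param gravity resting acceleration vector, in g.
#' @param seed RNG seed.
#' @return A `raw_accel` data frame of `1440 * 60 * sample_rate` rows.
#' @export
render_raw_stream <- function(minute_ai, wear = !is.na(minute_ai),
                              window_start = as.POSIXct("2024-03-01 12:00:00",
                                                        tz = "UTC"),
                              sample_rate = 20, gravity = c(0, 0, 1),
                              seed = 1L) {
  stopifnot(length(minute_ai) == MINUTES_PER_DAY,
            length(wear) == MINUTES_PER_DAY)
  nper <- as.integer(60 * sample_rate)
  n <- MINUTES_PER_DAY * nper
  sd_axis <- ifelse(is.na(minute_ai) | !wear, 0, minute_ai / 60)
  sdv <- rep(sd_axis, each = nper)
  with_seed(seed, {
    x <- stats::rnorm(n) * sdv + gravity[1L]
    y <- stats::rnorm(n) * sdv + gravity[2L]
    z <- stats::rnorm(n) * sdv + gravity[3L]
    tm <- window_start + (seq_len(n) - 0.5) / sample_rate
    as_raw_accel(data.frame(time = tm, x = x, y = y, z = z),
                 sample_rate = sample_rate,
                 tz = attr(window_start, "tzone") %||% "UTC")
  })
}

#' Render several consecutive days as one stream
#'
#' @param ai n_days x 1440 matrix (rows = consecutive days).
#' @param wear logical matrix of the same shape.
#' @param start_noon POSIXct noon of the first day.
#' @inheritParams render_raw_stream
#' @return A `raw_accel` data frame covering all days.
#' @export
render_raw_days <- function(ai, wear = !is.na(ai),
                            start_noon = as.POSIXct("2024-03-01 12:00:00",
                                                    tz = "UTC"),
                            sample_rate = 20, gravity = c(0, 0, 1),
                            seed = 1L) {
  blocks <- lapply(seq_len(nrow(ai)), function(d) {
    render_raw_stream(ai[d, ], wear[d, ],
                      window_start = start_noon + (d - 1L) * 86400,
                      sample_rate = sample_rate, gravity = gravity,
                      seed = seed + d - 1L)
  })
  out <- do.call(rbind, blocks)
  as_raw_accel(out, sample_rate = sample_rate,
               tz = attr(start_noon, "tzone") %||% "UTC")
}

#' Generate a synthetic cohort with events and deterioration
#'
#' Simulates `n_patients` monitored patients. A fraction `event_rate`
#' experiences one ER/RH event in the window where a full prediction
#' history exists; of those, `predictable_fraction` decline gradually
#' (deterioration onset `onset_days_before` days before the event) while
#' the rest worsen abruptly, with no antecedent signal — the undetectable
#' case. Per-patient amplitudes vary lognormally, reflecting how much
#' absolute activity differs between individuals.
#'
#' @param n_patients number of patients.
#' @param n_days monitored days per patient.
#' @param event_rate probability a patient has an ER/RH event.
#' @param predictable_fraction fraction of events preceded by gradual
#'   deterioration.
#' @param onset_days_before length of the pre-event decline, days
#'   (kept within the 30-day prediction horizon).
#' @param amplitude_decay_rate,regularity_decay_rate deterioration
#'   strengths passed to [patient_scenario()].
#' @param seed cohort RNG seed (per-patient seeds are derived from it).
#' @return A list: `scenarios` (list of [patient_scenario()]), `events`
#'   (data frame `patient_id,day_index,kind`), `truth` (data frame
#'   `patient_id,event_day,predictable`).
#' @export
generate_cohort <- function(n_patients = 16, n_days = 60, event_rate = 0.5,
                            predictable_fraction = 0.7,
                            onset_days_before = 21,
                            amplitude_decay_rate = 0.06,
                            regularity_decay_rate = 10,
                            seed = 1L) {
  stopifnot(onset_days_before <= 30, n_days >= 40)
  with_seed(seed, {
    ids <- sprintf("p%02d", seq_len(n_patients))
    has_event <- stats::runif(n_patients) < event_rate
    predictable <- has_event & stats::runif(n_patients) < predictable_fraction
    event_day <- ifelse(has_event,
                        sample(32:(n_days - 2L), n_patients, replace = TRUE),
                        NA_integer_)
    kind <- sample(c("ER", "RH"), n_patients, replace = TRUE)
    base_amp <- exp(stats::rnorm(n_patients, log(30), 0.35))
    pseeds <- seed + seq_len(n_patients)
    scenarios <- lapply(seq_len(n_patients), function(i) {
      det <- if (isTRUE(predictable[i])) {
        data.frame(event_day = event_day[i],
                   onset_days_before = onset_days_before,
                   amplitude_decay_rate = amplitude_decay_rate,
                   regularity_decay_rate = regularity_decay_rate)
      } else NULL
      ev <- if (isTRUE(has_event[i])) {
        data.frame(day = event_day[i], kind = kind[i])
      } else NULL
      patient_scenario(ids[i], n_days = n_days, base_amplitude = base_amp[i],
                       events = ev, deterioration = det, seed = pseeds[i])
    })
    events <- do.call(rbind, lapply(scenarios, function(s) {
      if (is.null(s$events)) return(NULL)
      data.frame(patient_id = s$patient_id, day_index = s$events$day,
                 kind = s$events$kind)
    }))
    if (is.null(events)) {
      events <- data.frame(patient_id = character(), day_index = integer(),
                           kind = character())
    }
    truth <- data.frame(patient_id = ids, event_day = event_day,
                        predictable = predictable)
    list(scenarios = scenarios, events = events, truth = truth)
  })
}

#' Run the minute-level pipeline over a synthetic cohort
#'
#' Convenience chain for validation studies: generate each scenario's
#' minute-AI series, build day records, compute daily metrics and trend
#' statistics, raise predictions and score them against the cohort's
#' event log.
#'
#' @param cohort output of [generate_cohort()].
#' @param profile a [criteria_profile()].
#' @param merge passed to [raise_predictions()].
#' @param horizon evaluation horizon in days.
#' @return A list: `eval` ([evaluate_predictions()] result), `preds`,
#'   `trend`, `metrics` (daily metrics data frame).
#' @export
run_synthetic_cohort <- function(cohort,
                                 profile = criteria_profile("proposed"),
                                 merge = TRUE, horizon = 30) {
  days <- unlist(lapply(cohort$scenarios,
                        function(s) scenario_day_records(generate_minute_ai(s))),
                 recursive = FALSE)
  metrics <- daily_metrics(days)
  trend <- build_trend_series(metrics)
  preds <- raise_predictions(trend, profile, merge = merge)
  ev <- evaluate_predictions(preds, cohort$events, horizon = horizon,
                             patients = cohort$truth$patient_id)
  list(eval = ev, preds = preds, trend = trend, metrics = metrics)
}
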