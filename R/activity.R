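#' Minute-wise activity index from raw acceleration
#'
#' The activity index (AI) of a minute summarises movement intensity from
#' the within-epoch variance of the raw signal: the minute is split into
#' sixty 1-second epochs; each epoch scores
#' \deqn{AI_{epoch} = \sqrt{\max\left(0,\;
#'   \frac{1}{3}\sum_{a \in \{x,y,z\}} (\sigma^2_a - \sigma^2_{noise})\right)}}
#' and the minute AI is the sum of the sixty epoch scores. Subtracting the
#' per-axis sensor noise variance makes a motionless wrist score (close to)
#' zero; with `noise_sd = 0` the index is homogeneous of degree one in the
#' acceleration amplitude. The AI definition is a pluggable default: any
#' function mapping one minute of samples to a non-negative scalar can be
#' substituted in [build_day_records()]-based workflows by computing
#' minute vectors externally and using [day_record()] directly.
#'
#' @param samples a data frame (or matrix) with columns/axes `x`, `y`,
#'   `z` and, for data frames, a `time` column; one minute of raw
#'   samples.
#' @param noise_sd per-axis sensor noise standard deviation in g
#'   (default 0, i.e. no calibration correction).
#' @param epoch_s epoch length in seconds.
#' @return A non-negative scalar, or `NA` for a minute with no samples.
#' @export
compute_minute_ai <- function(samples, noise_sd = 0, epoch_s = 1) {
  if (is.data.frame(samples)) {
    if (!is.null(samples$time) && nrow(samples) > 0) {
      off <- as.numeric(samples$time) - min(as.numeric(samples$time))
    } else {
      off <- seq_len(nrow(samples)) - 1  # fall back to sample order
    }
    acc <- cbind(samples$x, samples$y, samples$z)
  } else {
    acc <- as.matrix(samples)
    off <- seq_len(nrow(acc)) - 1
  }
  n <- nrow(acc)
  if (is.null(n) || n == 0L) return(NA_real_)
  epoch <- floor(off / epoch_s)
  ai <- 0
  for (e in unique(epoch)) {
    sub <- acc[epoch == e, , drop = FALSE]
    if (nrow(sub) < 2L) next
    v <- apply(sub, 2, stats::var) - noise_sd^2
    ai <- ai + sqrt(max(0, mean(v)))
  }
  ai
}

# Centred moving mean with NA-aware partial edge windows.
roll_mean_centered <- function(x, k) {
  half <- (k - 1L) %/% 2L
  n <- length(x)
  v <- ifelse(is.na(x), 0, x)
  cs <- cumsum(c(0, v))
  cn <- cumsum(c(0L, !is.na(x)))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  s <- cs[hi + 1L] - cs[lo]
  m <- cn[hi + 1L] - cn[lo]
  out <- s / m
  out[m == 0L] <- NA_real_
  out
}

# Vectorised minute-AI computation over a whole day block.
# Returns 1440 values, NA for minutes without any samples; epochs with a
# single sample contribute 0 (variance undefined).
minute_ai_profile <- function(block, noise_sd = 0, epoch_s = 1) {
  stopifnot(inherits(block, "accel_day_block"))
  s <- block$samples
  off <- as.numeric(s$time) - as.numeric(block$window_start)
  e <- floor(off / epoch_s)
  e <- pmin(pmax(e, 0), 86400 / epoch_s - 1)
  dt <- data.table::data.table(e = e, x = s$x, y = s$y, z = s$z)
  agg <- dt[, list(n = .N,
                   vx = stats::var(x), vy = stats::var(y), vz = stats::var(z)),
            by = "e"]
  ep_ai <- sqrt(pmax(0, ((agg$vx - noise_sd^2) + (agg$vy - noise_sd^2) +
                           (agg$vz - noise_sd^2)) / 3))
  ep_ai[agg$n < 2L] <- 0
  minute <- as.integer(agg$e * epoch_s) %/% 60L
  ai <- rep(NA_real_, MINUTES_PER_DAY)
  sums <- rowsum(ep_ai, minute)
  ai[as.integer(rownames(sums)) + 1L] <- sums[, 1L]
  ai
}

#' Sleep-detection parameters
#'
#' @param sleep_threshold AI level below which a minute is a sleep
#'   candidate. `NULL` (default) uses an adaptive threshold: 20% of the
#'   day's 90th AI percentile, floored at 0.1, which tracks the large
#'   between-patient differences in absolute activity level.
#' @param merge_gap sleep bouts separated by fewer than this many active
#'   minutes are merged (brief awakenings).
#' @param min_bout minimum bout length, in minutes, to count as sleep.
#' @param smooth_window width (minutes, odd) of the centred moving
#'   average applied to the AI series before thresholding.
#' @return A list of class `"sleep_params"`.
#' @export
sleep_params <- function(sleep_threshold = NULL, merge_gap = 20L,
                         min_bout = 60L, smooth_window = 11L) {
  stopifnot(merge_gap >= 0, min_bout >= 1, smooth_window %% 2 == 1)
  structure(list(sleep_threshold = sleep_threshold,
                 merge_gap = as.integer(merge_gap),
                 min_bout = as.integer(min_bout),
                 smooth_window = as.integer(smooth_window)),
            class = "sleep_params")
}

#' Detect sleep bouts in a day record
#'
#' A deterministic threshold-and-bout heuristic: minutes whose smoothed
#' (centred moving-average) AI falls below the threshold are sleep
#' candidates; candidate runs separated by short gaps are merged and only
#' bouts of at least `min_bout` minutes are kept. Sleep output is
#' descriptive (sleep duration, sleep/awake AI per hour) and does not
#' enter the trend statistics.
#'
#' @param day a [day_record()].
#' @param params a [sleep_params()] object.
#' @return A logical vector of length 1440 (`TRUE` = asleep).
#' @export
detect_sleep <- function(day, params = sleep_params()) {
  ai <- day$minute_ai
  sm <- roll_mean_centered(ai, params$smooth_window)
  thr <- params$sleep_threshold
  if (is.null(thr)) {
    q90 <- stats::quantile(ai, 0.9, na.rm = TRUE, names = FALSE)
    if (is.na(q90)) q90 <- 0
    thr <- max(0.2 * q90, 0.1)
  }
  cand <- !is.na(sm) & sm < thr
  # merge candidate runs separated by gaps shorter than merge_gap
  r <- rle(cand)
  if (length(r$values) > 2L) {
    interior <- which(!r$values & r$lengths < params$merge_gap)
    interior <- interior[interior > 1L & interior < length(r$values)]
    r$values[interior] <- TRUE
    cand <- inverse.rle(r)
    r <- rle(cand)
  }
  sleep <- rep(FALSE, MINUTES_PER_DAY)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (r$values[j] && r$lengths[j] >= params$min_bout) {
      sleep[starts[j]:ends[j]] <- TRUE
    }
  }
  sleep
}

#' Day-to-day regularity index
#'
#' The regularity index (RI) quantifies how similar today's minute-wise
#' activity pattern is to yesterday's, as the Pearson correlation of the
#' two 1440-minute AI vectors restricted to mutually worn minutes. RI
#' lies in [-1, 1]: near 1 for a patient repeating yesterday's daily
#' rhythm, near 0 for unrelated patterns, negative for anti-phase ones.
#' Like the AI, the definition is a pluggable default behind this
#' function's interface.
#'
#' @param day_i,day_prev two [day_record()]s, conventionally consecutive
#'   calendar days (the caller enforces consecutiveness).
#' @param min_mutual_minutes minimum number of mutually worn minutes for
#'   the correlation to be meaningful.
#' @return A scalar in [-1, 1], or `NA` when there are fewer than
#'   `min_mutual_minutes` mutually worn minutes or either restricted
#'   vector has zero variance.
#' @export
compute_ri <- function(day_i, day_prev, min_mutual_minutes = 720) {
  a <- day_i$minute_ai
  b <- day_prev$minute_ai
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < min_mutual_minutes) return(NA_real_)
  av <- a[ok]; bv <- b[ok]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(NA_real_)
  stats::cor(av, bv)
}

#' Per-day activity metrics
#'
#' Aggregates one valid day into the quantities the trend model consumes:
#' total AI (sum of the day's minute-wise AIs; missing worn minutes
#' contribute 0), the regularity index versus the previous calendar day,
#' sleep duration, and awake/sleep AI per hour.
#'
#' @param day a [day_record()].
#' @param day_prev the previous calendar day's record, or `NULL`; RI is
#'   `NA` unless `day_prev` is the valid day `day_index - 1`.
#' @param sleep logical 1440-vector from [detect_sleep()], or `NULL` to
#'   compute it here.
#' @param sleep_par a [sleep_params()] object.
#' @param ri_min_mutual passed to [compute_ri()].
#' @return A one-row data frame: `patient_id`, `day_index`, `valid`,
#'   `total_ai`, `ri`, `sleep_minutes`, `awake_ai_per_hour`,
#'   `sleep_ai_per_hour`, `nonwear_minutes`.
#' @export
compute_daily_metrics <- function(day, day_prev = NULL, sleep = NULL,
                                  sleep_par = sleep_params(),
                                  ri_min_mutual = 720) {
  if (!day$is_valid) {
    return(data.frame(patient_id = day$patient_id, day_index = day$day_index,
                      valid = FALSE, total_ai = NA_real_, ri = NA_real_,
                      sleep_minutes = NA_integer_,
                      awake_ai_per_hour = NA_real_,
                      sleep_ai_per_hour = NA_real_,
                      nonwear_minutes = as.integer(day$nonwear_minutes)))
  }
  if (is.null(sleep)) sleep <- detect_sleep(day, sleep_par)
  ai <- day$minute_ai
  worn <- day$wear_mask & !is.na(ai)
  total_ai <- sum(ai[worn])
  ri <- if (!is.null(day_prev) && isTRUE(day_prev$is_valid) &&
            day_prev$day_index == day$day_index - 1L) {
    compute_ri(day, day_prev, ri_min_mutual)
  } else NA_real_
  awake <- worn & !sleep
  asleep <- worn & sleep
  per_hour <- function(sel) {
    if (!any(sel)) return(NA_real_)
    sum(ai[sel]) / (sum(sel) / 60)
  }
  data.frame(patient_id = day$patient_id, day_index = day$day_index,
             valid = TRUE, total_ai = total_ai, ri = ri,
             sleep_minutes = sum(asleep),
             awake_ai_per_hour = per_hour(awake),
             sleep_ai_per_hour = per_hour(asleep),
             nonwear_minutes = as.integer(day$nonwear_minutes))
}

#' Daily metrics for a list of day records
#'
#' Applies [compute_daily_metrics()] across a patient's (or cohort's) day
#' records, pairing each day with its previous calendar day for the
#' regularity index. Records are grouped by `patient_id`; within a
#' patient, RI is `NA` on the first valid day and on any day whose
#' predecessor is invalid or absent.
#'
#' @param days a list of [day_record()] objects (one or more patients).
#' @param sleep_par a [sleep_params()] object.
#' @param ri_min_mutual passed to [compute_ri()].
#' @return A data frame, one row per day record, ordered by patient and
#'   day index (columns as in [compute_daily_metrics()]).
#' @export
daily_metrics <- function(days, sleep_par = sleep_params(),
                          ri_min_mutual = 720) {
  pid <- vapply(days, `[[`, character(1), "patient_id")
  out <- lapply(split(days, pid), function(pd) {
    di <- vapply(pd, `[[`, integer(1), "day_index")
    pd <- pd[order(di)]
    di <- sort(di)
    rows <- lapply(seq_along(pd), function(k) {
      prev_k <- match(di[k] - 1L, di)
      compute_daily_metrics(pd[[k]],
                            day_prev = if (!is.na(prev_k)) pd[[prev_k]] else NULL,
                            sleep_par = sleep_par,
                            ri_min_mutual = ri_min_mutual)
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}
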