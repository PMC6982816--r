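# Independent brute-force reimplementations used as oracles. These are
# deliberately plain (scalar loops, no shared code with the package
# internals) so agreement is evidence, not tautology.

# Activity index of one minute of samples: 1-s epochs, per-axis variance,
# noise-corrected mean, sqrt, summed.
oracle_minute_ai <- function(df, noise_sd = 0) {
  off <- as.numeric(df$time) - min(as.numeric(df$time))
  epoch <- floor(off)
  total <- 0
  for (e in sort(unique(epoch))) {
    sub <- df[epoch == e, , drop = FALSE]
    if (nrow(sub) < 2) next
    vx <- sum((sub$x - mean(sub$x))^2) / (nrow(sub) - 1)
    vy <- sum((sub$y - mean(sub$y))^2) / (nrow(sub) - 1)
    vz <- sum((sub$z - mean(sub$z))^2) / (nrow(sub) - 1)
    v <- ((vx - noise_sd^2) + (vy - noise_sd^2) + (vz - noise_sd^2)) / 3
    total <- total + sqrt(max(0, v))
  }
  total
}

# Trend statistics from a QoA series on a consecutive day grid, scalar.
oracle_trend <- function(q) {
  n <- length(q)
  dq <- rep(NA_real_, n)
  wq <- rep(NA_real_, n)
  dwq <- rep(NA_real_, n)
  sdq <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i >= 2 && !is.na(q[i]) && !is.na(q[i - 1]) && q[i - 1] != 0) {
      dq[i] <- (q[i] - q[i - 1]) / q[i - 1] * 100
    }
    if (i >= 4 && !anyNA(q[(i - 3):i])) {
      wq[i] <- 0.4 * q[i] + 0.3 * q[i - 1] + 0.2 * q[i - 2] + 0.1 * q[i - 3]
    }
  }
  for (i in seq_len(n)) {
    if (i >= 2 && !is.na(wq[i]) && !is.na(wq[i - 1]) && wq[i - 1] != 0) {
      dwq[i] <- (wq[i] - wq[i - 1]) / wq[i - 1] * 100
    }
    if (i >= 7 && !anyNA(dq[(i - 6):i])) sdq[i] <- sum(dq[(i - 6):i])
  }
  list(delta_qoa = dq, wqoa = wq, delta_wqoa = dwq, sum_delta_qoa = sdq)
}

# Count of negative values in a window, NA = non-drop.
oracle_drop_count <- function(w) {
  n <- 0L
  for (v in w) if (!is.na(v) && v < 0) n <- n + 1L
  n
}

# Confusion counts by exhaustive double loop over (prediction, event).
oracle_confusion <- function(preds, events, horizon = 30) {
  ev <- events[events$kind %in% c("ER", "RH"), , drop = FALSE]
  tp <- 0L; fp <- 0L
  for (i in seq_len(nrow(preds))) {
    hit <- FALSE
    for (j in seq_len(nrow(ev))) {
      if (preds$patient_id[i] == ev$patient_id[j] &&
          ev$day_index[j] > preds$day_index[i] &&
          ev$day_index[j] <= preds$day_index[i] + horizon) hit <- TRUE
    }
    if (hit) tp <- tp + 1L else fp <- fp + 1L
  }
  fn <- 0L
  for (j in seq_len(nrow(ev))) {
    seen <- FALSE
    for (i in seq_len(nrow(preds))) {
      if (preds$patient_id[i] == ev$patient_id[j] &&
          preds$day_index[i] >= ev$day_index[j] - horizon &&
          preds$day_index[i] < ev$day_index[j]) seen <- TRUE
    }
    if (!seen) fn <- fn + 1L
  }
  c(tp = tp, fp = fp, fn = fn)
}

# --- fixture builders ---------------------------------------------------

# A raw_accel stream of constant sampling with given per-minute axis sd
# (vector recycled over minutes); returns the in-memory stream object.
make_stream <- function(minute_sd, rate = 5, start = "2024-03-01 12:00:00",
                        seed = 1, gravity = c(0, 0, 1)) {
  nper <- 60 * rate
  n <- length(minute_sd) * nper
  set.seed(seed)
  sdv <- rep(minute_sd, each = nper)
  t0 <- as.POSIXct(start, tz = "UTC")
  qoatrend:::as_raw_accel(
    data.frame(time = t0 + (seq_len(n) - 0.5) / rate,
               x = rnorm(n) * sdv + gravity[1],
               y = rnorm(n) * sdv + gravity[2],
               z = rnorm(n) * sdv + gravity[3]),
    sample_rate = rate, tz = "UTC")
}

# A day_record with the given number of non-wear minutes at the front.
make_day <- function(patient_id = "p", day_index = 0, nonwear = 0,
                     ai_level = 1, partial = FALSE) {
  wear <- rep(TRUE, 1440)
  if (nonwear > 0) wear[seq_len(nonwear)] <- FALSE
  ai <- rep(ai_level, 1440)
  ai[!wear] <- NA
  day_record(patient_id, day_index, NA, ai, wear, partial = partial)
}

# A hand-made trend data frame for criteria tests (only the columns the
# predictor reads).
make_trend <- function(day_index, delta_wqoa, sum_delta_qoa,
                       patient_id = "p") {
  data.frame(patient_id = patient_id, day_index = day_index,
             qoa = NA_real_, delta_qoa = NA_real_, wqoa = NA_real_,
             delta_wqoa = delta_wqoa, sum_delta_qoa = sum_delta_qoa)
}
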