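test_that("minute AI is zero for constant signal and null under calibration", {
  t0 <- as.POSIXct("2024-03-01 12:00:00", tz = "UTC")
  const <- data.frame(time = t0 + (0:1199 + 0.5) / 20,
                      x = 0.2, y = -0.1, z = 0.98)
  expect_equal(compute_minute_ai(const), 0)

  set.seed(42)
  noise_sd <- 0.05
  noisy <- data.frame(time = t0 + (0:1199 + 0.5) / 20,
                      x = rnorm(1200, 0, noise_sd),
                      y = rnorm(1200, 0, noise_sd),
                      z = 1 + rnorm(1200, 0, noise_sd))
  ai <- compute_minute_ai(noisy, noise_sd = noise_sd)
  # calibration removes most of the pure-noise index; the residual is the
  # folded sampling error of 1-s variance estimates, well below the
  # uncorrected value
  ai_raw <- compute_minute_ai(noisy, noise_sd = 0)
  expect_gt(ai_raw, 60 * noise_sd * 0.8)
  expect_lt(ai, 0.3 * ai_raw)
})

test_that("minute AI matches the brute-force oracle on structured signal", {
  t0 <- as.POSIXct("2024-03-01 12:00:00", tz = "UTC")
  tt <- (0:1199 + 0.5) / 20
  sine <- data.frame(time = t0 + tt,
                     x = sin(2 * pi * 2 * tt), y = 0.1, z = 1)
  expect_equal(compute_minute_ai(sine), oracle_minute_ai(sine),
               tolerance = 1e-9)

  set.seed(7)
  mixed <- data.frame(time = t0 + tt,
                      x = rnorm(1200, 0, 0.3) + sin(2 * pi * tt),
                      y = rnorm(1200, 0, 0.1),
                      z = 1 + rnorm(1200, 0, 0.2))
  expect_equal(compute_minute_ai(mixed, noise_sd = 0.1),
               oracle_minute_ai(mixed, noise_sd = 0.1), tolerance = 1e-9)
})

test_that("vectorised day profile agrees with the per-minute oracle", {
  sds <- c(0.05, 0.2, 0, 0.4, 0.1)
  stream <- make_stream(sds, rate = 20, seed = 8)
  # pad to a sliceable day: treat as first 5 minutes of the day
  block <- slice_noon_days(stream, "2024-03-01")[[1]]
  prof <- qoatrend:::minute_ai_profile(block)
  off <- as.numeric(stream$time) - as.numeric(block$window_start)
  for (m in 0:4) {
    sub <- stream[off >= m * 60 & off < (m + 1) * 60, ]
    expect_equal(prof[m + 1], oracle_minute_ai(sub), tolerance = 1e-9)
  }
  expect_true(all(is.na(prof[6:1440])))
})

test_that("AI is homogeneous: scaling acceleration scales the index", {
  t0 <- as.POSIXct("2024-03-01 12:00:00", tz = "UTC")
  set.seed(9)
  tt <- (0:1199 + 0.5) / 20
  df <- data.frame(time = t0 + tt, x = rnorm(1200, 0, 0.2),
                   y = rnorm(1200, 0, 0.3), z = 1 + rnorm(1200, 0, 0.1))
  k <- 3.7
  scaled <- df
  scaled[c("x", "y", "z")] <- df[c("x", "y", "z")] * k
  expect_equal(compute_minute_ai(scaled), k * compute_minute_ai(df),
               tolerance = 1e-9)
})

test_that("sleep detection finds planted quiescence and handles extremes", {
  # all-zero day: a single 1440-minute bout
  d0 <- make_day(ai_level = 0)
  expect_equal(sum(detect_sleep(d0)), 1440L)

  # uniformly active day: no sleep
  dhi <- make_day(ai_level = 50)
  expect_equal(sum(detect_sleep(dhi)), 0L)

  # planted 02:00-08:00 quiescence (minutes 840-1199 on the noon grid)
  set.seed(10)
  ai <- 30 * exp(rnorm(1440, 0, 0.1))
  quiet <- 841:1200
  ai[quiet] <- 1 * exp(rnorm(length(quiet), 0, 0.1))
  d <- day_record("p", 0, NA, ai, rep(TRUE, 1440))
  sl <- which(detect_sleep(d))
  overlap <- length(intersect(sl, quiet)) / length(quiet)
  expect_gte(overlap, 0.9)
  expect_lt(length(setdiff(sl, quiet)) / length(quiet), 0.1)
})

test_that("regularity index behaves as a correlation across days", {
  set.seed(11)
  ai <- 20 * exp(rnorm(1440, 0, 0.2)) * default_circadian_profile()
  d1 <- day_record("p", 0, NA, ai, rep(TRUE, 1440))
  d2 <- day_record("p", 1, NA, ai, rep(TRUE, 1440))
  expect_equal(compute_ri(d2, d1), 1)

  # additive constant shift leaves the correlation at 1
  d3 <- day_record("p", 1, NA, ai + 5, rep(TRUE, 1440))
  expect_equal(compute_ri(d3, d1), 1, tolerance = 1e-12)

  # sinusoidal profile vs its 12 h rotation is in perfect anti-phase
  m <- 0:1439
  sine <- 10 + 5 * sin(2 * pi * m / 1440)
  rot <- 10 + 5 * sin(2 * pi * ((m + 720) %% 1440) / 1440)
  da <- day_record("p", 0, NA, sine, rep(TRUE, 1440))
  db <- day_record("p", 1, NA, rot, rep(TRUE, 1440))
  expect_equal(compute_ri(db, da), -1, tolerance = 1e-9)

  # symmetry
  set.seed(12)
  other <- ai * exp(rnorm(1440, 0, 0.3))
  d4 <- day_record("p", 1, NA, other, rep(TRUE, 1440))
  expect_equal(compute_ri(d4, d1), compute_ri(d1, d4))
})

test_that("regularity index is missing for sparse overlap or flat days", {
  wear_half <- rep(c(TRUE, FALSE), c(700, 740))
  ai_half <- ifelse(wear_half, 1 + sin(1:1440 / 40), NA)
  dh <- day_record("p", 0, NA, ai_half, wear_half)
  df <- make_day(day_index = 1, ai_level = 2)
  expect_true(is.na(compute_ri(dh, df)))          # < 720 mutual minutes
  expect_true(is.na(compute_ri(df, make_day())))  # zero variance
})

test_that("daily metrics aggregate worn, awake and asleep minutes correctly", {
  d <- make_day(ai_level = 1)
  m <- compute_daily_metrics(d, sleep = rep(FALSE, 1440))
  expect_equal(m$total_ai, 1440)
  expect_equal(m$awake_ai_per_hour, 60)
  expect_true(is.na(m$sleep_ai_per_hour))
  expect_equal(m$sleep_minutes, 0L)

  sleep <- rep(c(TRUE, FALSE), c(480, 960))
  m2 <- compute_daily_metrics(d, sleep = sleep)
  expect_equal(m2$sleep_ai_per_hour, 60)
  expect_equal(m2$awake_ai_per_hour, 60)
  expect_equal(m2$sleep_minutes, 480L)

  # total AI is permutation-invariant; RI is not
  set.seed(13)
  ai <- 10 * default_circadian_profile() * exp(rnorm(1440, 0, 0.2))
  perm <- sample(1440)
  dd <- day_record("p", 1, NA, ai, rep(TRUE, 1440))
  dp <- day_record("p", 1, NA, ai[perm], rep(TRUE, 1440))
  expect_equal(sum(dp$minute_ai), sum(dd$minute_ai))
  expect_lt(compute_ri(dp, day_record("p", 0, NA, ai, rep(TRUE, 1440))), 0.9)
})

test_that("daily_metrics pairs consecutive valid days for RI", {
  set.seed(14)
  mk <- function(i) day_record("p", i, NA,
                               10 * default_circadian_profile() *
                                 exp(rnorm(1440, 0, 0.15)),
                               rep(TRUE, 1440))
  days <- list(mk(0), mk(1), mk(3))  # day 2 absent
  met <- daily_metrics(days)
  expect_true(is.na(met$ri[met$day_index == 0]))
  expect_false(is.na(met$ri[met$day_index == 1]))
  expect_true(is.na(met$ri[met$day_index == 3]))  # gap breaks the pairing
})
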