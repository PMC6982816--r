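test_that("drop-day counting matches exhaustive enumeration", {
  expect_equal(drop_days_in_window(c(-1, -1, -1, -1, -1, 1, 1)), 5L)
  expect_equal(drop_days_in_window(rep(NA_real_, 7)), 0L)
  # all 2^7 sign patterns
  for (bits in 0:127) {
    w <- ifelse(bitwAnd(bits, 2^(0:6)) > 0, -1, 1)
    expect_equal(drop_days_in_window(w), oracle_drop_count(w))
  }
  # with NAs sprinkled in
  set.seed(31)
  for (i in 1:50) {
    w <- sample(c(-2.5, 0, 3, NA), 7, replace = TRUE)
    expect_equal(drop_days_in_window(w), oracle_drop_count(w))
  }
})

test_that("alert criteria combine drop days, 7-day sum and profile", {
  # days 0..9; day 9 has 5 drop days in its window
  dwq <- c(rep(NA, 3), -1, -1, -1, -1, -1, 1, 1)
  sdq <- c(rep(NA, 9), -35)
  tr <- make_trend(0:9, dwq, sdq)
  expect_equal(raise_predictions(tr, criteria_profile("proposed"))$day_index, 9L)

  # sum not beyond threshold -> no alert
  tr2 <- make_trend(0:9, dwq, c(rep(NA, 9), -29))
  expect_equal(nrow(raise_predictions(tr2, criteria_profile("proposed"))), 0L)

  # exactly 4 drop days: fails proposed ("more than 4"), passes loosened
  dwq4 <- c(rep(NA, 3), -1, -1, -1, -1, 1, 1, 1)
  tr3 <- make_trend(0:9, dwq4, c(rep(NA, 9), -35))
  expect_equal(nrow(raise_predictions(tr3, criteria_profile("proposed"))), 0L)
  expect_equal(raise_predictions(tr3, criteria_profile("loosened"))$day_index, 9L)

  # loosened threshold is -25: a -26 sum qualifies there only
  tr4 <- make_trend(0:9, dwq, c(rep(NA, 9), -26))
  expect_equal(nrow(raise_predictions(tr4, criteria_profile("proposed"))), 0L)
  expect_equal(nrow(raise_predictions(tr4, criteria_profile("loosened"))), 1L)
})

test_that("stricter profile needs three consecutive drops ending on the day", {
  base_sdq <- c(rep(NA, 9), -40)
  # 5 drop days but the last two days rise -> stricter refuses
  dwq_a <- c(rep(NA, 3), -1, -1, -1, -1, -1, 1, 1)
  tr_a <- make_trend(0:9, dwq_a, base_sdq)
  expect_equal(nrow(raise_predictions(tr_a, criteria_profile("stricter"))), 0L)
  expect_equal(nrow(raise_predictions(tr_a, criteria_profile("proposed"))), 1L)

  # same drop count with the run ending on the alert day -> qualifies
  dwq_b <- c(rep(NA, 3), 1, 1, -1, -1, -1, -1, -1)
  tr_b <- make_trend(0:9, dwq_b, base_sdq)
  expect_equal(raise_predictions(tr_b, criteria_profile("stricter"))$day_index, 9L)
})

test_that("no alert can precede day 7 after discharge", {
  dwq <- rep(-1, 10)
  sdq <- rep(-50, 10)
  tr <- make_trend(0:9, dwq, sdq)
  p <- raise_predictions(tr, criteria_profile("proposed"), merge = FALSE)
  expect_true(all(p$day_index >= 7L))
})

test_that("consecutive qualifying days merge into one episode", {
  dwq <- c(rep(NA, 3), rep(-1, 12))
  sdq <- c(rep(NA, 8), rep(-45, 3), NA, rep(-45, 3))
  tr <- make_trend(0:14, dwq, sdq)
  merged <- raise_predictions(tr, criteria_profile("proposed"), merge = TRUE)
  all_days <- raise_predictions(tr, criteria_profile("proposed"), merge = FALSE)
  expect_equal(nrow(all_days), 6L)
  expect_equal(merged$day_index, c(8L, 12L))   # two runs, anchored at starts
  expect_equal(merged$episode_id, c(1L, 2L))
})

test_that("profiles are monotone: stricter within proposed within loosened", {
  set.seed(32)
  for (i in 1:30) {
    n <- 40
    dwq <- ifelse(runif(n) < 0.15, NA, rnorm(n, -2, 8))
    sdq <- ifelse(runif(n) < 0.2, NA, rnorm(n, -15, 18))
    tr <- make_trend(0:(n - 1), dwq, sdq)
    q_strict <- qualifying_days(tr, criteria_profile("stricter"))$day_index
    q_prop <- qualifying_days(tr, criteria_profile("proposed"))$day_index
    q_loose <- qualifying_days(tr, criteria_profile("loosened"))$day_index
    expect_true(all(q_strict %in% q_prop))
    expect_true(all(q_prop %in% q_loose))
  }
})

test_that("prediction is deterministic and respects missing statistics", {
  set.seed(33)
  dwq <- rnorm(30, -3, 5)
  sdq <- rnorm(30, -25, 15)
  tr <- make_trend(0:29, dwq, sdq)
  p1 <- raise_predictions(tr, criteria_profile("proposed"))
  p2 <- raise_predictions(tr, criteria_profile("proposed"))
  expect_identical(p1, p2)

  # wiping the 7-day sum silences all alerts (fail-silent on missing data)
  tr_na <- make_trend(0:29, dwq, rep(NA_real_, 30))
  expect_equal(nrow(raise_predictions(tr_na, criteria_profile("proposed"))), 0L)
})

test_that("custom profiles validate their thresholds", {
  p <- criteria_profile("custom", min_drop_days = 2,
                        sum_dqoa_threshold = -10)
  expect_s3_class(p, "criteria_profile")
  expect_error(criteria_profile("nonsense"), "unknown profile")
  expect_error(criteria_profile("x", min_drop_days = 0,
                                sum_dqoa_threshold = -5))
  expect_error(criteria_profile("x", min_drop_days = 2,
                                sum_dqoa_threshold = 5))
})
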