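test_that("raw CSV round-trips through the dialect reader", {
  stream <- make_stream(rep(0.1, 3), rate = 5, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_raw_accel(stream, f)
  back <- read_raw_accel(f)
  expect_equal(nrow(back), nrow(stream))
  expect_equal(back$x, stream$x, tolerance = 1e-6)
  expect_lt(max(abs(as.numeric(back$time) - as.numeric(stream$time))), 0.011)
})

test_that("reader rejects malformed files and tolerates empty ones", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,x,y", "2024-03-01T12:00:00.00,0,0"), f)
  expect_error(read_raw_accel(f), "missing required column")

  writeLines(c("timestamp,x,y,z", "not-a-time,0,0,1"), f)
  expect_error(read_raw_accel(f), "unparseable timestamp at data row 1")

  writeLines(c("timestamp,x,y,z",
               "2024-03-01T12:00:01.00,0,0,1",
               "2024-03-01T12:00:00.00,0,0,1"), f)
  expect_error(read_raw_accel(f), "not in increasing order")
  expect_silent(sorted <- read_raw_accel(f, on_unsorted = "sort"))
  expect_false(is.unsorted(sorted$time))

  writeLines(character(), f)
  expect_warning(empty <- read_raw_accel(f), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("noon-to-noon slicing respects boundaries and loses no samples", {
  # 36 h at 1 sample/min starting at midnight -> partial + full block
  t0 <- as.POSIXct("2024-03-01 00:00:00", tz = "UTC")
  n <- 36 * 60
  stream <- qoatrend:::as_raw_accel(
    data.frame(time = t0 + (seq_len(n) - 1) * 60, x = 0, y = 0, z = 1),
    sample_rate = 1 / 60, tz = "UTC")
  blocks <- slice_noon_days(stream, "2024-03-01")
  expect_length(blocks, 2L)
  expect_true(blocks[[1]]$partial)   # 00:00-12:00 tail of day -1
  expect_false(blocks[[2]]$partial)  # full noon-to-noon day 0
  expect_equal(blocks[[1]]$day_index, -1L)
  expect_equal(blocks[[2]]$day_index, 0L)
  expect_equal(sum(vapply(blocks, function(b) nrow(b$samples), integer(1))), n)

  # exactly 48 h from noon -> 2 full blocks, day indices 0 and 1
  stream2 <- qoatrend:::as_raw_accel(
    data.frame(time = t0 + 12 * 3600 + (seq_len(48 * 60) - 1) * 60,
               x = 0, y = 0, z = 1),
    sample_rate = 1 / 60, tz = "UTC")
  blocks2 <- slice_noon_days(stream2, "2024-03-01")
  expect_length(blocks2, 2L)
  expect_false(any(vapply(blocks2, `[[`, logical(1), "partial")))
  expect_equal(vapply(blocks2, `[[`, integer(1), "day_index"), c(0L, 1L))
})

test_that("slicing is independent of file chunking", {
  stream <- make_stream(rep(c(0.1, 0.2), 720), rate = 2, seed = 3)
  cut <- nrow(stream) %/% 3
  a <- stream[seq_len(cut), ]
  b <- stream[(cut + 1):nrow(stream), ]
  restitch <- function(df) qoatrend:::as_raw_accel(df, sample_rate = 2, tz = "UTC")
  whole <- slice_noon_days(stream, "2024-03-01")
  parts <- c(slice_noon_days(restitch(a), "2024-03-01"),
             slice_noon_days(restitch(b), "2024-03-01"))
  n_whole <- sum(vapply(whole, function(x) nrow(x$samples), integer(1)))
  n_parts <- sum(vapply(parts, function(x) nrow(x$samples), integer(1)))
  expect_equal(n_whole, nrow(stream))
  expect_equal(n_parts, nrow(stream))
})

test_that("non-wear detection flags sustained flat runs only", {
  # active day with a 90-minute flat gap at minutes 301-390
  sds <- rep(0.1, 1440)
  gap <- 301:390
  sds[gap] <- 0
  stream <- make_stream(sds, rate = 5, seed = 4)
  block <- slice_noon_days(stream, "2024-03-01")[[1]]
  wear <- detect_nonwear(block)
  expect_equal(which(!wear), gap)

  # a 10-minute flat period stays wear (below the 30-min run threshold)
  sds10 <- rep(0.1, 1440); sds10[100:109] <- 0
  wear10 <- detect_nonwear(slice_noon_days(make_stream(sds10, rate = 5, seed = 5),
                                           "2024-03-01")[[1]])
  expect_true(all(wear10))

  # motionless full day -> everything non-wear
  flat <- detect_nonwear(slice_noon_days(make_stream(rep(0, 1440), rate = 5),
                                         "2024-03-01")[[1]])
  expect_false(any(flat))
})

test_that("non-wear detection is invariant to time and axis offsets", {
  sds <- rep(0.1, 1440); sds[201:290] <- 0
  stream <- make_stream(sds, rate = 5, seed = 6)
  wear1 <- detect_nonwear(slice_noon_days(stream, "2024-03-01")[[1]])

  shifted <- stream
  shifted$time <- shifted$time + 5 * 86400
  shifted$x <- shifted$x + 0.37
  shifted$z <- shifted$z - 1.2
  shifted <- qoatrend:::as_raw_accel(shifted, sample_rate = 5, tz = "UTC")
  wear2 <- detect_nonwear(slice_noon_days(shifted, "2024-03-06")[[1]])
  expect_identical(wear1, wear2)
})

test_that("valid-day rule: strictly more than one hour off-wrist invalidates", {
  expect_true(make_day(nonwear = 60)$is_valid)
  expect_false(make_day(nonwear = 61)$is_valid)
  expect_false(make_day(nonwear = 0, partial = TRUE)$is_valid)

  # consecutive-run variant: 2 x 40-min gaps pass, one 61-min run fails
  wear <- rep(TRUE, 1440)
  wear[c(1:40, 701:740)] <- FALSE
  ai <- rep(1, 1440); ai[!wear] <- NA
  d <- day_record("p", 0, NA, ai, wear)
  expect_false(is_valid_day(d, rule = "cumulative"))
  expect_true(is_valid_day(d, rule = "consecutive"))
})

test_that("minute-AI CSV round-trips day records", {
  d1 <- make_day("a", 0, nonwear = 10, ai_level = 2)
  d2 <- make_day("a", 1, nonwear = 0, ai_level = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_minute_ai(list(d1, d2), f)
  back <- read_minute_ai(f)
  expect_length(back, 2L)
  expect_equal(back[[1]]$minute_ai, d1$minute_ai)
  expect_equal(back[[1]]$wear_mask, d1$wear_mask)
  expect_equal(back[[2]]$day_index, 1L)
  expect_true(back[[2]]$is_valid)
})
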