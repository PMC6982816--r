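#' Describe the CSV dialect of a raw accelerometer export
#'
#' Raw recordings are consumed as plain CSV with one row per sample
#' (vendor-tool exports of wrist devices typically look like
#' \code{timestamp,x,y,z} with ISO-8601 timestamps and accelerations in g).
#' A dialect object names the columns and the timestamp format so exports
#' from different tools can be read without editing files.
#'
#' @param time_col,x_col,y_col,z_col column names in the CSV.
#' @param time_format timestamp format string for [strptime()], or `NULL`
#'   to auto-detect common ISO-8601 variants (`"T"` or space separator,
#'   optional fractional seconds).
#' @param decimal decimal separator used in the file.
#' @param tz time zone the clock timestamps are interpreted in. Timestamps
#'   are treated as local wall-clock time; the default fixed zone avoids
#'   daylight-saving reinterpretation of the 1440-minute day grid.
#' @param sample_rate nominal sampling rate in Hz.
#' @return A list of class `"accel_dialect"`.
#' @seealso [read_raw_accel()]
#' @export
accel_dialect <- function(time_col = "timestamp", x_col = "x", y_col = "y",
                          z_col = "z", time_format = NULL, decimal = ".",
                          tz = "UTC", sample_rate = 20) {
  stopifnot(sample_rate > 0)
  structure(list(time_col = time_col, x_col = x_col, y_col = y_col,
                 z_col = z_col, time_format = time_format,
                 decimal = decimal, tz = tz, sample_rate = sample_rate),
            class = "accel_dialect")
}

# Parse character timestamps quickly: second-resolution prefixes are
# memoised through unique() (a day has <= 86400 distinct seconds, far fewer
# than its 1.7M samples), fractional parts are appended numerically.
parse_accel_times <- function(x, dialect) {
  if (inherits(x, "POSIXct")) return(x)
  x <- as.character(x)
  fmt <- dialect$time_format
  if (is.null(fmt)) {
    probe <- x[1L]
    sep <- if (grepl("T", probe, fixed = TRUE)) "T" else " "
    fmt <- paste0("%Y-%m-%d", sep, "%H:%M:%S")
  }
  # fixed-width fast path: split at the seconds boundary
  head_len <- nchar(format(as.POSIXct("2000-01-02 03:04:05", tz = "UTC"),
                           sub("%OS[0-9]*", "%S", fmt)))
  sec_str <- substr(x, 1L, head_len)
  frac_str <- substr(x, head_len + 1L, nchar(x))
  u <- unique(sec_str)
  parsed_u <- as.POSIXct(u, tz = dialect$tz, format = sub("%OS[0-9]*", "%S", fmt))
  out <- parsed_u[match(sec_str, u)]
  has_frac <- nzchar(frac_str)
  if (any(has_frac)) {
    frac <- rep(0, length(x))
    frac[has_frac] <- as.numeric(sub(",", ".", paste0("0", frac_str[has_frac]),
                                     fixed = TRUE))
    out <- out + frac
  }
  out
}

#' Read a raw tri-axial accelerometer CSV
#'
#' Reads a whole-deployment export (possibly spanning weeks) into a
#' `raw_accel` data frame with columns `time` (POSIXct), `x`, `y`, `z`
#' (acceleration in g).
#'
#' @param path path to the CSV file.
#' @param dialect an [accel_dialect()] describing the file layout.
#' @param on_unsorted what to do when timestamps are not strictly
#'   increasing: `"error"` (default) or `"sort"`.
#' @param verbose report the row count via [message()].
#' @return A data frame of class `c("raw_accel", "data.frame")` with
#'   attributes `sample_rate` and `tz`. An empty file yields a 0-row
#'   stream with a warning.
#' @export
read_raw_accel <- function(path, dialect = accel_dialect(),
                           on_unsorted = c("error", "sort"),
                           verbose = FALSE) {
  on_unsorted <- match.arg(on_unsorted)
  stopifnot(file.exists(path))
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path, dec = dialect$decimal, showProgress = FALSE,
                        colClasses = stats::setNames(list(dialect$time_col),
                                                     "character"))),
    error = function(e) data.table::data.table()
  )
  if (nrow(dt) == 0L) {
    warning("empty raw accelerometer file: ", path)
    return(empty_raw_stream(dialect))
  }
  need <- c(dialect$time_col, dialect$x_col, dialect$y_col, dialect$z_col)
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols)) {
    stop("raw CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tm <- parse_accel_times(dt[[dialect$time_col]], dialect)
  if (anyNA(tm)) {
    bad <- which(is.na(tm))[1L]
    stop("unparseable timestamp at data row ", bad, ": '",
         dt[[dialect$time_col]][bad], "'")
  }
  out <- data.frame(time = tm,
                    x = as.numeric(dt[[dialect$x_col]]),
                    y = as.numeric(dt[[dialect$y_col]]),
                    z = as.numeric(dt[[dialect$z_col]]))
  if (is.unsorted(out$time)) {
    if (on_unsorted == "error") {
      stop("timestamps are not in increasing order (set on_unsorted = \"sort\" to reorder)")
    }
    out <- out[order(out$time), , drop = FALSE]
    row.names(out) <- NULL
  }
  if (verbose) message("read ", nrow(out), " samples from ", path)
  as_raw_accel(out, sample_rate = dialect$sample_rate, tz = dialect$tz)
}

as_raw_accel <- function(df, sample_rate = 20, tz = "UTC") {
  structure(df, class = c("raw_accel", "data.frame"),
            sample_rate = sample_rate, tz = tz)
}

empty_raw_stream <- function(dialect = accel_dialect()) {
  as_raw_accel(data.frame(time = as.POSIXct(character(), tz = dialect$tz),
                          x = numeric(), y = numeric(), z = numeric()),
               sample_rate = dialect$sample_rate, tz = dialect$tz)
}

#' Write a raw stream back to CSV
#'
#' Inverse of [read_raw_accel()]; mainly used to materialise synthetic
#' streams in the same dialect the ingest stage consumes.
#'
#' @param stream a `raw_accel` data frame.
#' @param path output path.
#' @param dialect an [accel_dialect()]; column names and timestamp format
#'   are taken from it (`NULL` format writes ISO-8601 with 2 fractional
#'   digits).
#' @return `path`, invisibly.
#' @export
write_raw_accel <- function(stream, path, dialect = accel_dialect()) {
  fmt <- dialect$time_format %||% "%Y-%m-%dT%H:%M:%OS2"
  out <- data.table::data.table(
    ts = format(stream$time, fmt, tz = attr(stream, "tz") %||% dialect$tz),
    x = stream$x, y = stream$y, z = stream$z)
  data.table::setnames(out, c(dialect$time_col, dialect$x_col,
                              dialect$y_col, dialect$z_col))
  data.table::fwrite(out, path, dec = dialect$decimal)
  invisible(path)
}

#' Slice a raw stream into noon-to-noon days
#'
#' A monitoring day runs from 12:00 of one calendar day to 12:00 of the
#' next, so that a full night's sleep sits inside a single day record.
#' Day indices count days since the discharge date (day 0 starts at noon
#' of the discharge date).
#'
#' @param stream a `raw_accel` data frame (see [read_raw_accel()]).
#' @param discharge_date the hospital discharge date (`Date` or
#'   `"YYYY-MM-DD"`); the day-index origin.
#' @return A list of `accel_day_block` objects, each with elements
#'   `day_index`, `window_start` (POSIXct at 12:00), `samples` (the rows
#'   falling in the window) and `partial` (`TRUE` when the stream starts
#'   or ends inside the window). Days with no samples at all are absent
#'   from the list.
#' @details Only the first and last block of a stream can be partial:
#'   interior coverage holes are a wear-time matter and are handled by
#'   [detect_nonwear()] (minutes without samples count as non-wear).
#' @export
slice_noon_days <- function(stream, discharge_date) {
  stopifnot(nrow(stream) > 0L)
  tz <- attr(stream, "tz") %||% "UTC"
  rate <- attr(stream, "sample_rate") %||% 20
  noon0 <- as.POSIXct(paste(as.character(as.Date(discharge_date)), "12:00:00"),
                      tz = tz)
  off <- as.numeric(stream$time) - as.numeric(noon0)
  di <- floor(off / 86400)
  idx <- split(seq_len(nrow(stream)), di)
  days <- as.integer(names(idx))
  n <- length(idx)
  t_first <- as.numeric(stream$time[idx[[1L]][1L]])
  t_last <- as.numeric(stream$time[idx[[n]][length(idx[[n]])]])
  blocks <- vector("list", n)
  for (k in seq_len(n)) {
    ws <- noon0 + days[k] * 86400
    partial <- (k == 1L && t_first - as.numeric(ws) > 1) ||
      (k == n && as.numeric(ws) + 86400 - 1 / rate - t_last > 1)
    samples <- stream[idx[[k]], , drop = FALSE]
    row.names(samples) <- NULL
    blocks[[k]] <- structure(
      list(day_index = days[k], window_start = ws, samples = samples,
           partial = partial, sample_rate = rate),
      class = "accel_day_block")
  }
  blocks
}

#' Non-wear detection parameters
#'
#' A minute is "stationary" when, on every axis, the within-minute
#' standard deviation is below `sd_threshold` and the range is below
#' `range_threshold`. Runs of at least `min_run` consecutive stationary
#' (or sample-free) minutes are classified as non-wear; shorter still
#' periods are treated as quiet wear (e.g. reading, dozing).
#'
#' @param sd_threshold per-axis standard-deviation ceiling, in g.
#' @param range_threshold per-axis range (max minus min) ceiling, in g.
#' @param min_run minimum run length, in minutes.
#' @return A list of class `"nonwear_params"`.
#' @export
nonwear_params <- function(sd_threshold = 0.013, range_threshold = 0.05,
                           min_run = 30L) {
  stopifnot(sd_threshold > 0, range_threshold > 0, min_run >= 1)
  structure(list(sd_threshold = sd_threshold,
                 range_threshold = range_threshold,
                 min_run = as.integer(min_run)),
            class = "nonwear_params")
}

#' Detect off-wrist minutes in a day block
#'
#' @param block an `accel_day_block` from [slice_noon_days()].
#' @param params a [nonwear_params()] object.
#' @return A logical vector of length 1440 (`TRUE` = worn), indexed by
#'   minute since the noon window start.
#' @details The detector is invariant to shifting all timestamps and to
#'   adding a constant offset to any axis (only dispersion within the
#'   minute matters). Minutes containing no samples are always non-wear.
#' @export
detect_nonwear <- function(block, params = nonwear_params()) {
  stopifnot(inherits(block, "accel_day_block"), nrow(block$samples) >= 1L)
  s <- block$samples
  m <- floor((as.numeric(s$time) - as.numeric(block$window_start)) / 60)
  m <- pmin(pmax(m, 0), MINUTES_PER_DAY - 1L)
  dt <- data.table::data.table(m = as.integer(m), x = s$x, y = s$y, z = s$z)
  agg <- dt[, list(n = .N,
                   sx = stats::sd(x), sy = stats::sd(y), sz = stats::sd(z),
                   rx = max(x) - min(x), ry = max(y) - min(y),
                   rz = max(z) - min(z)),
            by = "m"]
  stationary <- rep(FALSE, MINUTES_PER_DAY)  # minutes w/o samples handled below
  has_data <- rep(FALSE, MINUTES_PER_DAY)
  mi <- agg$m + 1L
  has_data[mi] <- TRUE
  ok_var <- agg$n >= 2L &
    agg$sx < params$sd_threshold & agg$sy < params$sd_threshold &
    agg$sz < params$sd_threshold &
    agg$rx < params$range_threshold & agg$ry < params$range_threshold &
    agg$rz < params$range_threshold
  stationary[mi] <- ok_var
  candidate <- stationary | !has_data
  nonwear <- rep(FALSE, MINUTES_PER_DAY)
  r <- rle(candidate)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in seq_along(r$values)) {
    if (r$values[j] && r$lengths[j] >= params$min_run) {
      nonwear[starts[j]:ends[j]] <- TRUE
    }
  }
  nonwear <- nonwear | !has_data
  !nonwear
}

#' Construct a single day record
#'
#' A day record holds one noon-to-noon day of minute-wise activity
#' indices together with the wear mask and validity flag. Minute entries
#' are `NA` exactly where the device was not worn.
#'
#' @param patient_id patient identifier.
#' @param day_index integer day index (days since discharge; day 0 starts
#'   at noon of the discharge date).
#' @param window_start POSIXct of the window's 12:00 start (may be `NA`
#'   for records built from pre-aggregated minute data).
#' @param minute_ai numeric vector of length 1440, `NA` where not worn.
#' @param wear_mask logical vector of length 1440, `TRUE` = worn.
#' @param partial `TRUE` when the stream did not cover the full window.
#' @return An object of class `"day_record"`.
#' @export
day_record <- function(patient_id, day_index, window_start = NA,
                       minute_ai, wear_mask, partial = FALSE) {
  stopifnot(length(minute_ai) == MINUTES_PER_DAY,
            length(wear_mask) == MINUTES_PER_DAY,
            is.logical(wear_mask))
  minute_ai <- as.numeric(minute_ai)
  if (any(!is.na(minute_ai) & !wear_mask)) {
    stop("minute_ai must be NA wherever wear_mask is FALSE")
  }
  if (any(!is.na(minute_ai) & minute_ai < 0)) {
    stop("minute_ai must be non-negative")
  }
  rec <- structure(
    list(patient_id = as.character(patient_id),
         day_index = as.integer(day_index),
         window_start = window_start,
         minute_ai = minute_ai,
         wear_mask = wear_mask,
         partial = isTRUE(partial),
         nonwear_minutes = sum(!wear_mask)),
    class = "day_record")
  rec$is_valid <- is_valid_day(rec)
  rec
}

#' Apply the valid-day rule
#'
#' A day is analysable only when the device was off the wrist for at most
#' one hour; "more than one hour" is read strictly, so exactly 60
#' non-wear minutes still count as valid. Partial first/last days are
#' never valid: a total activity sum over fewer than 1440 minutes is not
#' comparable day to day.
#'
#' @param day a [day_record()].
#' @param max_nonwear_minutes non-wear budget, in minutes.
#' @param rule `"cumulative"` (default) counts all non-wear minutes in
#'   the day; `"consecutive"` only disqualifies a day whose longest
#'   single non-wear run exceeds the budget.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_day <- function(day, max_nonwear_minutes = 60,
                         rule = c("cumulative", "consecutive")) {
  rule <- match.arg(rule)
  if (isTRUE(day$partial)) return(FALSE)
  nw <- !day$wear_mask
  bad <- if (rule == "cumulative") {
    sum(nw)
  } else {
    r <- rle(nw)
    if (any(r$values)) max(r$lengths[r$values]) else 0L
  }
  bad <= max_nonwear_minutes
}

#' @export
print.day_record <- function(x, ...) {
  cat(sprintf("<day_record> patient %s, day %d: %s%s, %d non-wear min, total AI %.1f\n",
              x$patient_id, x$day_index,
              if (x$is_valid) "valid" else "invalid",
              if (x$partial) " (partial)" else "",
              x$nonwear_minutes, sum(x$minute_ai, na.rm = TRUE)))
  invisible(x)
}

#' Build day records from a raw stream
#'
#' Convenience wrapper chaining [slice_noon_days()], [detect_nonwear()]
#' and the minute-wise activity-index computation into a list of
#' [day_record()] objects.
#'
#' @param stream a `raw_accel` data frame.
#' @param discharge_date the discharge date (day-index origin).
#' @param patient_id patient identifier attached to every record.
#' @param nonwear a [nonwear_params()] object.
#' @param noise_sd per-axis sensor noise standard deviation (g) removed
#'   from the activity index; see [compute_minute_ai()].
#' @return A list of `day_record` objects in day order.
#' @export
build_day_records <- function(stream, discharge_date, patient_id = "p1",
                              nonwear = nonwear_params(), noise_sd = 0) {
  blocks <- slice_noon_days(stream, discharge_date)
  lapply(blocks, function(b) {
    wm <- detect_nonwear(b, params = nonwear)
    ai <- minute_ai_profile(b, noise_sd = noise_sd)
    ai[!wm] <- NA_real_
    day_record(patient_id, b$day_index, b$window_start, ai, wm, b$partial)
  })
}

#' Summarise day records
#'
#' @param days a list of [day_record()] objects.
#' @return A data frame with one row per day: `patient_id`, `day_index`,
#'   `valid`, `nonwear_minutes`, `partial`.
#' @export
day_summary <- function(days) {
  data.frame(
    patient_id = vapply(days, `[[`, character(1), "patient_id"),
    day_index = vapply(days, `[[`, integer(1), "day_index"),
    valid = vapply(days, `[[`, logical(1), "is_valid"),
    nonwear_minutes = vapply(days, function(d) as.integer(d$nonwear_minutes),
                             integer(1)),
    partial = vapply(days, `[[`, logical(1), "partial"))
}

#' Write and read minute-wise activity indices as CSV
#'
#' The long format (`patient_id,day_index,minute_of_day,ai,worn`) is the
#' interchange format between the ingest stage and downstream analysis;
#' `minute_of_day` counts minutes since the noon window start (0–1439).
#'
#' @param days a list of [day_record()] objects.
#' @param path CSV path.
#' @return `write_minute_ai()` returns `path` invisibly;
#'   `read_minute_ai()` returns a list of `day_record` objects.
#' @export
write_minute_ai <- function(days, path) {
  dt <- data.table::rbindlist(lapply(days, function(d) {
    data.table::data.table(
      patient_id = d$patient_id, day_index = d$day_index,
      minute_of_day = 0:(MINUTES_PER_DAY - 1L),
      ai = d$minute_ai, worn = d$wear_mask)
  }))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_minute_ai
#' @export
read_minute_ai <- function(path) {
  dt <- data.table::fread(path, showProgress = FALSE)
  need <- c("patient_id", "day_index", "minute_of_day", "ai", "worn")
  if (!all(need %in% names(dt))) {
    stop("minute-AI CSV must have columns: ", paste(need, collapse = ", "))
  }
  keys <- unique(dt[, c("patient_id", "day_index")])
  data.table::setorder(keys, patient_id, day_index)
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- dt[dt$patient_id == keys$patient_id[i] &
                dt$day_index == keys$day_index[i], ]
    ai <- rep(NA_real_, MINUTES_PER_DAY)
    worn <- rep(FALSE, MINUTES_PER_DAY)
    mi <- sub$minute_of_day + 1L
    ai[mi] <- sub$ai
    worn[mi] <- as.logical(sub$worn)
    ai[!worn] <- NA_real_
    day_record(keys$patient_id[i], keys$day_index[i], NA, ai, worn)
  })
}
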