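#' Quality of activity
#'
#' The QoA score combines the amount of daily activity with its
#' day-to-day regularity:
#' \deqn{QoA_i = Total\_AI_i \cdot (1 + RI_i)}
#' so a day of typical volume performed on a typical schedule scores
#' higher than the same volume performed erratically ("act it right"
#' beats "act it more"). With RI in [-1, 1] the regularity factor spans
#' [0, 2].
#'
#' @param total_ai non-negative total AI of the day (sum of the 1440
#'   minute-wise AIs).
#' @param ri regularity index versus the previous day, in [-1, 1].
#' @return `total_ai * (1 + ri)`; `NA` when either input is missing
#'   (there is no regularity default for a first or post-gap day).
#' @export
qoa <- function(total_ai, ri) {
  ifelse(is.na(total_ai) | is.na(ri), NA_real_, total_ai * (1 + ri))
}

#' Day-over-day percent change of QoA
#'
#' \deqn{\Delta QoA_i = (QoA_i - QoA_{i-1}) / QoA_{i-1} \times 100}
#' Percentages are carried on the x100 scale throughout (a 30% drop is
#' -30, not -0.3), which is the scale the alert thresholds compare on.
#'
#' @param qoa_i,qoa_prev QoA of day i and of day i-1.
#' @return Percent change; `NA` when either value is missing or
#'   `qoa_prev` is zero (degenerate reference day).
#' @export
delta_qoa <- function(qoa_i, qoa_prev) {
  ifelse(is.na(qoa_i) | is.na(qoa_prev) | qoa_prev == 0,
         NA_real_, (qoa_i - qoa_prev) / qoa_prev * 100)
}

#' Weighted 4-day running QoA
#'
#' \deqn{WQoA_i = 0.4\,QoA_i + 0.3\,QoA_{i-1} + 0.2\,QoA_{i-2} + 0.1\,QoA_{i-3}}
#' The fixed weights (they are part of the published model, not tuning
#' knobs) sum to one, so a constant series is left unchanged while
#' recent days dominate.
#'
#' @param qoa_i,qoa_im1,qoa_im2,qoa_im3 QoA on days i, i-1, i-2, i-3.
#' @return The weighted sum; `NA` when any of the four is missing.
#' @export
wqoa <- function(qoa_i, qoa_im1, qoa_im2, qoa_im3) {
  0.4 * qoa_i + 0.3 * qoa_im1 + 0.2 * qoa_im2 + 0.1 * qoa_im3
}

#' Day-over-day percent change of WQoA
#'
#' \deqn{\Delta WQoA_i = (WQoA_i - WQoA_{i-1}) / WQoA_{i-1} \times 100}
#'
#' @param wqoa_i,wqoa_prev WQoA of day i and of day i-1.
#' @return Percent change on the x100 scale; `NA` on missing input or a
#'   zero reference.
#' @export
delta_wqoa <- function(wqoa_i, wqoa_prev) {
  ifelse(is.na(wqoa_i) | is.na(wqoa_prev) | wqoa_prev == 0,
         NA_real_, (wqoa_i - wqoa_prev) / wqoa_prev * 100)
}

#' Cumulative 7-day percent change of QoA
#'
#' \deqn{\sum\Delta QoA_i = \sum_{j=0}^{6} \Delta QoA_{i-j}}
#' the total percentage of QoA change over the most recent seven days.
#'
#' @param deltas the seven most recent daily \eqn{\Delta QoA} values,
#'   ending at day i.
#' @return Their sum; `NA` when any of the seven is missing.
#' @export
sum_delta_qoa <- function(deltas) {
  stopifnot(length(deltas) == 7L)
  if (anyNA(deltas)) NA_real_ else sum(deltas)
}

#' Build the trend-statistic series for each patient
#'
#' Expands each patient's daily metrics onto a complete calendar grid of
#' day indices and computes QoA, \eqn{\Delta QoA}, WQoA,
#' \eqn{\Delta WQoA} and \eqn{\sum\Delta QoA} with strict missing-data
#' propagation: every difference or window requires calendar-consecutive
#' valid days, so an invalid or absent day suppresses \eqn{\Delta QoA}
#' on the following day and \eqn{\sum\Delta QoA} for a further seven
#' days. Because all derived statistics are percent changes, the series
#' is invariant to rescaling a patient's overall activity level — the
#' self-referential property that makes patients comparable to
#' themselves rather than to each other.
#'
#' @param metrics a data frame from [daily_metrics()] (columns
#'   `patient_id`, `day_index`, `valid`, `total_ai`, `ri`).
#' @param ri_missing policy for days whose RI is missing: `"na"`
#'   (default) leaves QoA undefined that day; `"zero"` substitutes
#'   RI = 0.
#' @return A data frame with one row per patient-day on the calendar
#'   grid: `patient_id`, `day_index`, `qoa`, `delta_qoa`, `wqoa`,
#'   `delta_wqoa`, `sum_delta_qoa` (missing values as `NA`).
#' @export
build_trend_series <- function(metrics, ri_missing = c("na", "zero")) {
  ri_missing <- match.arg(ri_missing)
  stopifnot(all(c("patient_id", "day_index", "valid", "total_ai", "ri")
                %in% names(metrics)))
  out <- lapply(split(metrics, metrics$patient_id), function(m) {
    m <- m[order(m$day_index), , drop = FALSE]
    grid <- seq(min(m$day_index), max(m$day_index))
    n <- length(grid)
    pos <- match(grid, m$day_index)
    valid <- !is.na(pos) & m$valid[pos]
    total_ai <- ifelse(valid, m$total_ai[pos], NA_real_)
    ri <- ifelse(valid, m$ri[pos], NA_real_)
    if (ri_missing == "zero") ri[valid & is.na(ri)] <- 0
    q <- qoa(total_ai, ri)
    q_lag <- c(NA_real_, q[-n])
    dq <- delta_qoa(q, q_lag)
    wq <- rep(NA_real_, n)
    if (n >= 4L) {
      wq[4:n] <- wqoa(q[4:n], q[3:(n - 1)], q[2:(n - 2)], q[1:(n - 3)])
    }
    wq_lag <- c(NA_real_, wq[-n])
    dwq <- delta_wqoa(wq, wq_lag)
    # right-aligned 7-day sum; NA anywhere in the window propagates
    sdq <- if (n >= 7L) {
      as.numeric(stats::filter(dq, rep(1, 7), sides = 1))
    } else rep(NA_real_, n)
    data.frame(patient_id = m$patient_id[1L], day_index = grid,
               qoa = q, delta_qoa = dq, wqoa = wq, delta_wqoa = dwq,
               sum_delta_qoa = sdq)
  })
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}
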