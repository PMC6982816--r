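#' Alert criteria profiles
#'
#' A criteria profile packages the thresholds that turn a trend series
#' into readmission alerts. The three named profiles are:
#' \describe{
#'   \item{`proposed`}{more than 4 of the past 7 days with WQoA dropping
#'     (\eqn{\Delta WQoA_i < 0}), and \eqn{\sum\Delta QoA_i} below -30
#'     on the day.}
#'   \item{`loosened`}{more than 3 drop days in the past 7, and
#'     \eqn{\sum\Delta QoA_i} below -25.}
#'   \item{`stricter`}{the proposed conditions plus three consecutive
#'     drop days ending on (and including) the alert day.}
#' }
#' "More than n" is strict, so the proposed profile needs at least 5
#' drop days and the loosened one at least 4. "Dropping" means WQoA fell
#' versus the previous day (\eqn{\Delta WQoA < 0}), not that
#' \eqn{\Delta WQoA} itself decreased.
#'
#' @param name one of `"proposed"`, `"loosened"`, `"stricter"`, or any
#'   other label when the threshold arguments are given explicitly.
#' @param min_drop_days alert requires strictly more than this many drop
#'   days in the window.
#' @param window look-back window length in days (the published model
#'   uses 7).
#' @param sum_dqoa_threshold alert requires \eqn{\sum\Delta QoA} strictly
#'   below this (negative, x100 percent scale).
#' @param require_consecutive_drops if > 0, additionally require
#'   \eqn{\Delta WQoA < 0} on this many consecutive days ending at the
#'   alert day.
#' @return An object of class `"criteria_profile"`.
#' @export
criteria_profile <- function(name = c("proposed", "loosened", "stricter"),
                             min_drop_days = NULL, window = 7L,
                             sum_dqoa_threshold = NULL,
                             require_consecutive_drops = NULL) {
  presets <- list(
    proposed = list(min_drop_days = 4L, sum_dqoa_threshold = -30,
                    require_consecutive_drops = 0L),
    loosened = list(min_drop_days = 3L, sum_dqoa_threshold = -25,
                    require_consecutive_drops = 0L),
    stricter = list(min_drop_days = 4L, sum_dqoa_threshold = -30,
                    require_consecutive_drops = 3L))
  if (length(name) > 1L) name <- name[1L]
  p <- presets[[name]] %||% list()
  min_drop_days <- as.integer(min_drop_days %||% p$min_drop_days)
  sum_dqoa_threshold <- as.numeric(sum_dqoa_threshold %||% p$sum_dqoa_threshold)
  require_consecutive_drops <-
    as.integer(require_consecutive_drops %||% p$require_consecutive_drops %||% 0L)
  if (!length(min_drop_days) || !length(sum_dqoa_threshold)) {
    stop("unknown profile '", name,
         "': supply min_drop_days and sum_dqoa_threshold explicitly")
  }
  stopifnot(min_drop_days > 0, min_drop_days <= window,
            sum_dqoa_threshold < 0, require_consecutive_drops >= 0)
  structure(list(name = name, min_drop_days = min_drop_days,
                 window = as.integer(window),
                 sum_dqoa_threshold = sum_dqoa_threshold,
                 require_consecutive_drops = require_consecutive_drops),
            class = "criteria_profile")
}

#' @export
print.criteria_profile <- function(x, ...) {
  cat(sprintf(
    "<criteria_profile> %s: > %d drop days in %d, sum(dQoA) < %g%s\n",
    x$name, x$min_drop_days, x$window, x$sum_dqoa_threshold,
    if (x$require_consecutive_drops > 0)
      sprintf(", %d consecutive drops", x$require_consecutive_drops) else ""))
  invisible(x)
}

#' Count WQoA drop days in a 7-day window
#'
#' @param delta_wqoa the window of \eqn{\Delta WQoA} values ending at the
#'   evaluation day (missing values count as non-dropping — a day whose
#'   statistic does not exist cannot witness a drop).
#' @return Integer count of days with \eqn{\Delta WQoA < 0}.
#' @export
drop_days_in_window <- function(delta_wqoa) {
  sum(!is.na(delta_wqoa) & delta_wqoa < 0)
}

# Vectorised per-day criteria evaluation for one patient's trend rows
# (assumed a complete consecutive day_index grid, as produced by
# build_trend_series). Returns a logical qualifying-day vector.
criteria_met_series <- function(trend, profile) {
  n <- nrow(trend)
  dwq <- trend$delta_wqoa
  sdq <- trend$sum_delta_qoa
  drops <- !is.na(dwq) & dwq < 0
  w <- profile$window
  # right-aligned rolling drop count; days before the grid count as non-drop
  cs <- cumsum(c(rep(0L, w), as.integer(drops)))
  dropcount <- cs[seq_len(n) + w] - cs[seq_len(n)]
  met <- trend$day_index >= 7L &
    dropcount > profile$min_drop_days &
    !is.na(sdq) & sdq < profile$sum_dqoa_threshold
  k <- profile$require_consecutive_drops
  if (k > 0L) {
    csd <- cumsum(c(rep(0L, k), as.integer(drops)))
    consec <- (csd[seq_len(n) + k] - csd[seq_len(n)]) == k
    met <- met & consec
  }
  met
}

#' Raise readmission alerts from a trend series
#'
#' Evaluates the criteria profile on every day of each patient's trend
#' series (alerts start on day 7 after discharge at the earliest: the
#' model needs a 7-day history before its first window is defined) and
#' returns the alert days. With `merge = TRUE` (default) a maximal run
#' of consecutive qualifying days is collapsed to a single alert episode
#' anchored at the run's first day; with `merge = FALSE` every
#' qualifying day becomes its own prediction row.
#'
#' @param trend a trend data frame from [build_trend_series()].
#' @param profile a [criteria_profile()].
#' @param merge collapse consecutive qualifying days into episodes?
#' @return A data frame of predictions: `patient_id`, `day_index`,
#'   `profile`, `episode_id` (episodes numbered per patient).
#' @export
raise_predictions <- function(trend, profile = criteria_profile("proposed"),
                              merge = TRUE) {
  out <- lapply(split(trend, trend$patient_id), function(tr) {
    tr <- tr[order(tr$day_index), , drop = FALSE]
    met <- criteria_met_series(tr, profile)
    if (!any(met)) {
      return(data.frame(patient_id = character(), day_index = integer(),
                        profile = character(), episode_id = integer()))
    }
    qd <- tr$day_index[met]
    episode <- cumsum(c(1L, diff(qd) != 1L))
    if (merge) {
      first <- !duplicated(episode)
      qd <- qd[first]
      episode <- episode[first]
    }
    data.frame(patient_id = tr$patient_id[1L], day_index = qd,
               profile = profile$name, episode_id = episode)
  })
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

#' Qualifying days under a profile
#'
#' The un-merged day-level view of [raise_predictions()]; useful for
#' comparing profiles (qualifying-day sets are nested: stricter within
#' proposed within loosened).
#'
#' @inheritParams raise_predictions
#' @return A data frame `patient_id`, `day_index` of all qualifying
#'   days.
#' @export
qualifying_days <- function(trend, profile = criteria_profile("proposed")) {
  p <- raise_predictions(trend, profile, merge = FALSE)
  p[, c("patient_id", "day_index")]
}
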