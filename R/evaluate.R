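#' Read a clinical event log
#'
#' Events are ER visits (`"ER"`), rehospitalizations (`"RH"`) and routine
#' outpatient visits (`"OPD"`). ER/RH events are the clinical endpoints
#' alerts are scored against; OPD visits are annotations only (a
#' treatment change at an OPD visit can explain a false positive, but
#' never reclassifies it).
#'
#' @param path CSV with columns `patient_id,day_index,kind`.
#' @return A data frame of events.
#' @export
read_events <- function(path) {
  ev <- data.table::fread(path, showProgress = FALSE)
  need <- c("patient_id", "day_index", "kind")
  if (!all(need %in% names(ev))) {
    stop("events CSV must have columns: ", paste(need, collapse = ", "))
  }
  ev$patient_id <- as.character(ev$patient_id)
  bad <- setdiff(unique(ev$kind), c("ER", "RH", "OPD"))
  if (length(bad)) stop("unknown event kind(s): ", paste(bad, collapse = ", "))
  as.data.frame(ev)
}

endpoint_events <- function(events) {
  events[events$kind %in% c("ER", "RH"), , drop = FALSE]
}

#' Label predictions against clinical events
#'
#' A prediction raised on day d is a true positive when an ER visit or
#' rehospitalization occurs within the next 30 days — strictly after the
#' alert day and at most `horizon` days later (d < e <= d + horizon);
#' otherwise it is a false positive. Several predictions may be credited
#' to the same event (each prediction is counted once).
#'
#' @param preds prediction data frame from [raise_predictions()].
#' @param events event data frame (see [read_events()]).
#' @param horizon prediction horizon in days.
#' @return `preds` with added columns `label` (`"TP"`/`"FP"`) and
#'   `opd_within` (`TRUE` when a routine OPD visit falls in the horizon —
#'   annotation of possible treatment-change false positives).
#' @export
classify_predictions <- function(preds, events, horizon = 30) {
  ep <- endpoint_events(events)
  opd <- events[events$kind == "OPD", , drop = FALSE]
  within <- function(d, ev_days) any(ev_days > d & ev_days <= d + horizon)
  n <- nrow(preds)
  label <- character(n)
  opd_within <- logical(n)
  for (i in seq_len(n)) {
    pevents <- ep$day_index[ep$patient_id == preds$patient_id[i]]
    label[i] <- if (within(preds$day_index[i], pevents)) "TP" else "FP"
    pods <- opd$day_index[opd$patient_id == preds$patient_id[i]]
    opd_within[i] <- within(preds$day_index[i], pods)
  }
  preds$label <- label
  preds$opd_within <- opd_within
  preds
}

#' Find unpredicted (false-negative) events
#'
#' An ER/RH event on day e is a false negative when no prediction was
#' raised in the 30 days before it (no alert day d with
#' e - horizon <= d < e). The window mirrors the true-positive window.
#'
#' @inheritParams classify_predictions
#' @return The subset of ER/RH event rows that were not predicted.
#' @export
find_unpredicted_events <- function(preds, events, horizon = 30) {
  ep <- endpoint_events(events)
  if (nrow(ep) == 0L) return(ep)
  fn <- vapply(seq_len(nrow(ep)), function(i) {
    d <- preds$day_index[preds$patient_id == ep$patient_id[i]]
    e <- ep$day_index[i]
    !any(d >= e - horizon & d < e)
  }, logical(1))
  ep[fn, , drop = FALSE]
}

#' Confusion metrics for alert evaluation
#'
#' From prediction-level true/false positives and event-level false
#' negatives:
#' sensitivity = 100 TP/(TP+FN), precision = 100 TP/(TP+FP),
#' miss rate = 100 - sensitivity, false discovery rate = 100 - precision.
#' There is no true-negative count — quiet days without an event are not
#' enumerable occasions — so specificity and fall-out are deliberately
#' not computed.
#'
#' @param tp,fp,fn non-negative integer counts.
#' @return An object of class `"readmission_metrics"`: the counts plus
#'   the four percentages at full precision (printing rounds to two
#'   decimals). Sensitivity and miss rate are `NA` when `tp + fn` is 0;
#'   precision and FDR are `NA` when no predictions were made.
#' @export
compute_metrics <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn,
                 sensitivity = sens, precision = prec,
                 miss_rate = 100 - sens,
                 false_discovery_rate = 100 - prec),
            class = "readmission_metrics")
}

#' @export
print.readmission_metrics <- function(x, digits = 2, ...) {
  cat(sprintf("Readmission alert metrics (TP=%d, FP=%d, FN=%d)\n",
              x$tp, x$fp, x$fn))
  fmt <- function(v) if (is.na(v)) "NA" else sprintf(paste0("%.", digits, "f%%"), v)
  cat("  sensitivity:          ", fmt(x$sensitivity), "\n")
  cat("  precision:            ", fmt(x$precision), "\n")
  cat("  miss rate:            ", fmt(x$miss_rate), "\n")
  cat("  false discovery rate: ", fmt(x$false_discovery_rate), "\n")
  invisible(x)
}

#' Evaluate predictions against a clinical event log
#'
#' Pools the per-prediction labels and per-event misses into a cohort
#' report: a per-patient summary table (actual events, predictions,
#' truly/falsely predicted, not predicted) with a Total row, and the
#' pooled confusion metrics.
#'
#' @inheritParams classify_predictions
#' @param patients optional character vector fixing the patient set (and
#'   row order); defaults to the union of patients seen in predictions
#'   and events.
#' @return An object of class `"readmission_eval"` with elements
#'   `per_patient` (data frame), `totals` (named counts), `metrics`
#'   ([compute_metrics()] result), `labelled` and `unpredicted` (the
#'   underlying row-level results).
#' @export
evaluate_predictions <- function(preds, events, horizon = 30,
                                 patients = NULL) {
  lab <- classify_predictions(preds, events, horizon)
  fn_events <- find_unpredicted_events(preds, events, horizon)
  ep <- endpoint_events(events)
  if (is.null(patients)) {
    patients <- sort(unique(c(preds$patient_id, events$patient_id)))
  }
  per <- data.frame(
    patient_id = patients,
    actual_events = vapply(patients, function(p)
      sum(ep$patient_id == p), integer(1)),
    predicted = vapply(patients, function(p)
      sum(lab$patient_id == p), integer(1)),
    truly_predicted = vapply(patients, function(p)
      sum(lab$patient_id == p & lab$label == "TP"), integer(1)),
    falsely_predicted = vapply(patients, function(p)
      sum(lab$patient_id == p & lab$label == "FP"), integer(1)),
    not_predicted = vapply(patients, function(p)
      sum(fn_events$patient_id == p), integer(1)),
    row.names = NULL)
  totals <- c(actual_events = sum(per$actual_events),
              predicted = sum(per$predicted),
              truly_predicted = sum(per$truly_predicted),
              falsely_predicted = sum(per$falsely_predicted),
              not_predicted = sum(per$not_predicted))
  structure(list(per_patient = per, totals = totals,
                 metrics = compute_metrics(tp = totals[["truly_predicted"]],
                                           fp = totals[["falsely_predicted"]],
                                           fn = totals[["not_predicted"]]),
                 labelled = lab, unpredicted = fn_events,
                 horizon = horizon),
            class = "readmission_eval")
}

#' @export
print.readmission_eval <- function(x, ...) {
  cat(sprintf("Readmission alert evaluation (%d-day horizon)\n", x$horizon))
  tab <- x$per_patient
  tot <- data.frame(patient_id = "Total", t(x$totals))
  names(tot) <- names(tab)
  print(rbind(tab, tot), row.names = FALSE)
  cat("\n")
  print(x$metrics)
  invisible(x)
}
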