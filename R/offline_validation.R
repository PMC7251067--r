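# Post-hoc validation chain: tetrode-wide spike merging with
# largest-spike censoring, an automated light-response criterion, the
# online/offline concordance table, and experiment-time accounting.

#' Merge per-wire detections over a tetrode with largest-spike censoring
#'
#' One action potential appears on several tetrode wires at slightly
#' different amplitudes, so naive per-wire detection counts it up to four
#' times. Offline, detections from all wires are merged and time-sorted,
#' and within any censoring window only the detection with the largest
#' absolute amplitude survives (greedy by amplitude; ties broken by
#' earlier time, then lower channel). The result has no two spikes closer
#' than the censoring window.
#'
#' @param per_channel_spikes a single data.frame of detections (columns
#'   `channel`, `timestamp`, `peak_amplitude`), or a list of per-wire
#'   data.frames to be concatenated.
#' @param censor_ms censoring window, milliseconds (default 0.75, shared
#'   with the online holdoff so online and offline counts compare
#'   directly).
#' @param sampling_rate samples per second of the timestamps.
#' @return the surviving detections, sorted by timestamp.
#' @export
merge_and_censor <- function(per_channel_spikes, censor_ms = 0.75,
                             sampling_rate = 30000) {
  if (is.data.frame(per_channel_spikes)) d <- per_channel_spikes
  else d <- do.call(rbind, per_channel_spikes)
  if (is.null(d) || !nrow(d)) return(d)
  censor <- ms_to_samples(censor_ms, sampling_rate)
  ord <- order(-abs(d$peak_amplitude), d$timestamp, d$channel)
  d <- d[ord, , drop = FALSE]
  kept_ts <- numeric(0)
  keep <- logical(nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!length(kept_ts) || all(abs(d$timestamp[i] - kept_ts) >= censor)) {
      keep[i] <- TRUE
      kept_ts <- c(kept_ts, d$timestamp[i])
    }
  }
  d <- d[keep, , drop = FALSE]
  d <- d[order(d$timestamp, d$channel), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Automated light-response criterion on a PETH
#'
#' Surrogate for the experimenter's online judgment: a histogram is
#' called light-responsive when the maximum count inside the short-latency
#' window exceeds the baseline (pre-event) mean by more than 3 baseline
#' standard deviations. With fewer than `min_events` accumulated events
#' the outcome is `"insufficient"` — neither positive nor negative.
#'
#' @param acc a [peth_accumulator()], or a list with fields `counts`
#'   (vector or `[channel, bin]` matrix), `edges` (ms) and `n_events`.
#' @param latency_window_ms response window relative to the event,
#'   default `c(0, 10)` ms (short-latency optogenetic responses).
#' @param baseline_window_ms baseline span; default the whole pre-event
#'   side.
#' @param channels channels summed into the histogram (default all — a
#'   tetrode is judged by all its wires together).
#' @param min_events minimum events for a judgment (default 10).
#' @return list with `outcome` (`"positive"`, `"negative"` or
#'   `"insufficient"`), `score` (z-like statistic), `peak_bin_ms`
#'   (lower edge of the maximal latency-window bin).
#' @export
light_response_criterion <- function(acc, latency_window_ms = c(0, 10),
                                     baseline_window_ms = NULL,
                                     channels = NULL, min_events = 10) {
  counts <- acc$counts
  if (is.matrix(counts)) {
    if (!is.null(channels)) counts <- counts[channels, , drop = FALSE]
    counts <- colSums(counts)
  }
  edges <- acc$edges
  lo <- edges[-length(edges)]
  hi <- edges[-1]
  if (is.null(baseline_window_ms)) baseline_window_ms <- c(edges[1], 0)
  lat <- lo >= latency_window_ms[1] & hi <= latency_window_ms[2]
  base <- lo >= baseline_window_ms[1] & hi <= baseline_window_ms[2]
  if (!any(lat) || !any(base))
    stop("latency and baseline windows must each cover at least one bin",
         call. = FALSE)
  if (acc$n_events < min_events)
    return(list(outcome = "insufficient", score = NA_real_,
                peak_bin_ms = NA_real_))
  mu <- mean(counts[base])
  sdev <- stats::sd(counts[base])
  peak <- max(counts[lat])
  peak_bin <- lo[lat][which.max(counts[lat])]
  score <- if (sdev > 0) (peak - mu) / sdev
           else if (peak > mu) Inf else 0
  list(outcome = if (peak > mu + 3 * sdev) "positive" else "negative",
       score = score, peak_bin_ms = peak_bin)
}

#' Build per-tetrode detection records
#'
#' @param session_id,tetrode_id identifiers (vectors, recycled).
#' @param online_positive,offline_positive logical vectors: light response
#'   judged online / established offline.
#' @return data.frame of class `detection_records`, one row per
#'   (session, tetrode).
#' @export
detection_records <- function(session_id, tetrode_id,
                              online_positive, offline_positive) {
  d <- data.frame(session_id = session_id, tetrode_id = tetrode_id,
                  online_positive = as.logical(online_positive),
                  offline_positive = as.logical(offline_positive))
  if (anyDuplicated(d[c("session_id", "tetrode_id")]))
    stop("detection records must be unique per (session, tetrode)",
         call. = FALSE)
  class(d) <- c("detection_records", "data.frame")
  d
}

#' Expand per-session confusion counts into detection records
#'
#' Turns a table with per-session `tp`, `fp`, `fn`, `tn` counts (one row
#' per recording session) into one boolean record per tetrode, so the
#' session-level bookkeeping of a printed concordance table can be fed to
#' [concordance()].
#'
#' @param counts data.frame with columns `session`, `tp`, `fp`, `fn`,
#'   `tn`.
#' @return a [detection_records()] data.frame.
#' @export
expand_session_counts <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    n <- r$tp + r$fp + r$fn + r$tn
    if (n == 0) return(NULL)
    data.frame(
      session_id = r$session,
      tetrode_id = seq_len(n),
      online_positive = rep(c(TRUE, TRUE, FALSE, FALSE),
                            c(r$tp, r$fp, r$fn, r$tn)),
      offline_positive = rep(c(TRUE, FALSE, TRUE, FALSE),
                             c(r$tp, r$fp, r$fn, r$tn)))
  })
  d <- do.call(rbind, rows)
  detection_records(d$session_id, d$tetrode_id,
                    d$online_positive, d$offline_positive)
}

#' Online/offline concordance table
#'
#' Cross-tabulates online against offline light-response judgments.
#' Sensitivity is `100 * tp / (tp + fn)`, specificity
#' `100 * tn / (tn + fp)`, computed in full precision; the print method
#' shows two decimals. With no offline-positive record sensitivity is
#' undefined (`NA`, reported as "undefined"), never silently 0; likewise
#' specificity.
#'
#' @param records a [detection_records()] data.frame (non-empty).
#' @return object of class `concordance_table` with fields `tp`, `fp`,
#'   `fn`, `tn`, `n_online_positive`, `sensitivity`, `specificity`
#'   (percent, full precision, `NA` when undefined).
#' @export
concordance <- function(records) {
  if (!nrow(records)) stop("no records", call. = FALSE)
  on <- records$online_positive
  off <- records$offline_positive
  tp <- sum(on & off); fp <- sum(on & !off)
  fn <- sum(!on & off); tn <- sum(!on & !off)
  structure(
    list(tp = tp, fp = fp, fn = fn, tn = tn,
         n_records = nrow(records),
         n_online_positive = tp + fp,
         n_offline_positive = tp + fn,
         sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
         specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_),
    class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat("Online vs offline light-response concordance\n")
  cat(sprintf("  TP %d  FP %d  FN %d  TN %d  (n = %d)\n",
              x$tp, x$fp, x$fn, x$tn, x$n_records))
  cat("  sensitivity:", fmt(x$sensitivity),
      " specificity:", fmt(x$specificity), "\n")
  invisible(x)
}

#' Experiment time budget
#'
#' The acute-recording protocol the accounting assumes: at each electrode
#' position, a settling wait (default 30 min) followed by a recording
#' (default 15 min); a fixed number of positions would be recorded per
#' animal without online feedback (default 10), and each recorded session
#' costs analysis time afterwards (default 30 min).
#'
#' @param n_animals number of animals.
#' @param actual_hours measured per-animal experiment hours with online
#'   feedback (waiting + recording, surgery excluded).
#' @param settle_min,record_min,positions_per_animal,analysis_min_per_session
#'   protocol constants, see above.
#' @return object of class `time_budget`.
#' @export
time_budget <- function(n_animals, actual_hours, settle_min = 30,
                        record_min = 15, positions_per_animal = 10,
                        analysis_min_per_session = 30) {
  if (!is_count(n_animals)) stop_field("n_animals", "must be > 0")
  if (length(actual_hours) != n_animals)
    stop_field("actual_hours", "needs one value per animal")
  if (any(c(settle_min, record_min, positions_per_animal,
            analysis_min_per_session, actual_hours) < 0))
    stop_field("time_budget", "all durations must be non-negative")
  structure(list(n_animals = as.integer(n_animals),
                 actual_hours = as.numeric(actual_hours),
                 settle_min = settle_min, record_min = record_min,
                 positions_per_animal = positions_per_animal,
                 analysis_min_per_session = analysis_min_per_session),
            class = "time_budget")
}

#' Experiment-time savings from online feedback
#'
#' Compares the exhaustive protocol (record every position) against the
#' measured per-animal hours when positions without an online light
#' response were skipped. Sessions actually recorded are recovered as
#' `actual_total / (settle + record)` and rounded to the nearest whole
#' session before computing sessions avoided.
#'
#' @param budget a [time_budget()].
#' @return object of class `time_savings_report`: `baseline_hours_per_animal`,
#'   `baseline_hours`, `actual_hours_total`, `recording_saved_h`,
#'   `sessions_recorded`, `sessions_avoided`, `analysis_saved_h`,
#'   `total_saved_h`.
#' @export
time_savings <- function(budget) {
  stopifnot(inherits(budget, "time_budget"))
  per_session_h <- (budget$settle_min + budget$record_min) / 60
  per_animal <- budget$positions_per_animal * per_session_h
  baseline <- budget$n_animals * per_animal
  actual <- sum(budget$actual_hours)
  if (actual > baseline)
    warning("actual experiment time exceeds the exhaustive baseline; ",
            "savings are negative", call. = FALSE)
  sessions_recorded <- round(actual / per_session_h)
  sessions_avoided <- budget$n_animals * budget$positions_per_animal -
    sessions_recorded
  analysis_saved <- sessions_avoided * budget$analysis_min_per_session / 60
  structure(
    list(baseline_hours_per_animal = per_animal,
         baseline_hours = baseline,
         actual_hours_total = actual,
         recording_saved_h = baseline - actual,
         sessions_recorded = sessions_recorded,
         sessions_avoided = sessions_avoided,
         analysis_saved_h = analysis_saved,
         total_saved_h = baseline - actual + analysis_saved),
    class = "time_savings_report")
}

#' @export
print.time_savings_report <- function(x, ...) {
  cat("Experiment-time accounting\n")
  cat(sprintf("  baseline: %.2f h (%.2f h/animal)\n",
              x$baseline_hours, x$baseline_hours_per_animal))
  cat(sprintf("  actual:   %.2f h  -> recording saved %.2f h\n",
              x$actual_hours_total, x$recording_saved_h))
  cat(sprintf("  sessions avoided: %d  -> analysis saved %.2f h\n",
              x$sessions_avoided, x$analysis_saved_h))
  cat(sprintf("  total saved: %.2f h\n", x$total_saved_h))
  invisible(x)
}
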