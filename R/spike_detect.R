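# Threshold-crossing spike discrimination with holdoff censoring.
# A detection opens when the signal strictly crosses the threshold (falls
# below it for negative polarity); the extremum of the supra-threshold run
# is the peak. After a detection no new one is accepted until the signal
# has re-crossed the threshold AND the holdoff dead time has elapsed since
# the previous peak, so one spike is never counted twice. Channel ids are
# 1-based everywhere user-facing.

#' Per-channel detection settings
#'
#' @param n_channels number of channels governed by this config.
#' @param threshold threshold in microvolts, one value (recycled) or one
#'   per channel. Negative polarity requires negative thresholds: raw
#'   (non-inverted) extracellular spikes are negative-going.
#' @param polarity `"negative"` (default) or `"positive"`.
#' @param holdoff_ms censoring dead time after each detected peak
#'   (default 0.75 ms, a conventional censoring period for extracellular
#'   units; the dead time itself is protocol-defined, its length is not).
#' @param disabled_channels 1-based channel ids excluded from detection,
#'   e.g. broken wires; accepts the range notation of
#'   [parse_channel_ranges()] or an integer vector.
#' @return object of class `threshold_config`.
#' @export
threshold_config <- function(n_channels, threshold = -50,
                             polarity = c("negative", "positive"),
                             holdoff_ms = 0.75, disabled_channels = integer()) {
  polarity <- match.arg(polarity)
  if (!is_count(n_channels)) stop_field("n_channels", "must be > 0")
  if (!is.numeric(holdoff_ms) || holdoff_ms < 0)
    stop_field("holdoff_ms", "must be >= 0")
  thr <- rep_len(as.numeric(threshold), n_channels)
  check_threshold_sign(thr, polarity)
  if (is.character(disabled_channels))
    disabled_channels <- parse_channel_ranges(disabled_channels)
  structure(
    list(n_channels = as.integer(n_channels), threshold = thr,
         polarity = polarity, holdoff_ms = holdoff_ms,
         disabled_channels = as.integer(sort(unique(disabled_channels)))),
    class = "threshold_config")
}

check_threshold_sign <- function(thr, polarity) {
  if (polarity == "negative" && any(thr >= 0))
    stop_field("threshold", "negative polarity requires threshold < 0")
  if (polarity == "positive" && any(thr <= 0))
    stop_field("threshold", "positive polarity requires threshold > 0")
  invisible(TRUE)
}

#' Adjust thresholds for one channel or all channels at once
#'
#' @param config a [threshold_config()].
#' @param channel a 1-based channel id, or `"all"`.
#' @param value new threshold in microvolts; its sign must match the
#'   configured polarity.
#' @return the updated config (other channels untouched).
#' @export
set_threshold <- function(config, channel, value) {
  stopifnot(inherits(config, "threshold_config"))
  check_threshold_sign(value, config$polarity)
  if (identical(channel, "all")) {
    config$threshold[] <- value
  } else {
    if (!is_count(channel) || channel > config$n_channels)
      stop_field("channel", "must be 'all' or a valid 1-based channel id")
    config$threshold[channel] <- value
  }
  config
}

#' Parse comma/dash channel range notation
#'
#' Disabled channels are listed either comma-separated or with dash
#' notation (`"1, 2, 3"` or `"1-3"`); both forms, mixed, are accepted and
#' whitespace is tolerated. An en dash is treated as a dash.
#'
#' @param text the range string; may be empty (empty set).
#' @return sorted integer vector of unique 1-based channel ids.
#' @export
parse_channel_ranges <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("–", "-", text)  # en dash
  tokens <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  tokens <- tokens[nzchar(tokens)]
  out <- integer()
  for (tok in tokens) {
    if (grepl("^[0-9]+$", tok)) {
      out <- c(out, as.integer(tok))
    } else if (grepl("^[0-9]+\\s*-\\s*[0-9]+$", tok)) {
      ab <- as.integer(strsplit(tok, "-", fixed = TRUE)[[1]])
      ab <- ab[!is.na(ab)]
      if (ab[1] > ab[2])
        stop("parse error in channel ranges: descending range '", tok, "'",
             call. = FALSE)
      out <- c(out, seq(ab[1], ab[2]))
    } else {
      stop("parse error in channel ranges: malformed token '", tok, "'",
           call. = FALSE)
    }
  }
  sort(unique(out))
}

# core state machine on one numeric vector; returns 1-based indices.
# For positive polarity the trace is negated so one code path serves both.
detect_vector <- function(x, threshold, holdoff_samples) {
  below <- x < threshold          # strict crossing
  if (!any(below)) return(NULL)
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs_s <- starts[r$values]
  runs_e <- ends[r$values]        # run still open at window end: closed here
  keep_s <- integer(); keep_e <- integer(); peaks <- integer()
  last_peak <- -Inf
  for (i in seq_along(runs_s)) {
    s <- runs_s[i]; e <- runs_e[i]
    if (s - last_peak < holdoff_samples) next  # crossing inside dead time
    seg <- x[s:e]
    p <- s + which.min(seg) - 1L   # earliest extremal sample on ties
    keep_s <- c(keep_s, s); keep_e <- c(keep_e, e); peaks <- c(peaks, p)
    last_peak <- p
  }
  if (!length(peaks)) return(NULL)
  data.frame(peak_index = peaks, excursion_start = keep_s,
             excursion_end = keep_e, peak_amplitude = x[peaks])
}

#' Detect spikes in an event-aligned window
#'
#' Runs the threshold/holdoff state machine independently on every enabled
#' channel. Because detection is per-window, overlapping trigger ROIs may
#' report the same spike under both events; online accumulation
#' deliberately does not deduplicate (that is the offline chain's job, see
#' [merge_and_censor()]).
#'
#' @param window an `aligned_window` from [extract_roi()], or any object
#'   with fields `samples`, `sampling_rate` and `start_timestamp`.
#' @param config a [threshold_config()] matching the window's channels.
#' @return data.frame with one row per detection: `channel`, `peak_index`
#'   (1-based within the window), `timestamp` (absolute sample index of
#'   the peak), `peak_amplitude` (microvolts), `excursion_start`,
#'   `excursion_end` (1-based window indices of the supra-threshold run).
#'   Zero rows when nothing crosses threshold.
#' @export
detect_spikes <- function(window, config) {
  stopifnot(inherits(config, "threshold_config"))
  m <- window$samples
  if (nrow(m) != config$n_channels)
    stop_field("config", "channel count does not match window")
  hold <- ms_to_samples(config$holdoff_ms, window$sampling_rate)
  sgn <- if (config$polarity == "negative") 1 else -1
  out <- vector("list", nrow(m))
  for (ch in seq_len(nrow(m))) {
    if (ch %in% config$disabled_channels) next
    d <- detect_vector(sgn * m[ch, ], sgn * config$threshold[ch], hold)
    if (is.null(d)) next
    d$peak_amplitude <- sgn * d$peak_amplitude
    d$channel <- ch
    out[[ch]] <- d
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(channel = integer(), peak_index = integer(),
                      timestamp = numeric(), peak_amplitude = numeric(),
                      excursion_start = integer(), excursion_end = integer()))
  d <- do.call(rbind, out)
  d$timestamp <- window$start_timestamp + d$peak_index - 1
  d[order(d$timestamp, d$channel),
    c("channel", "peak_index", "timestamp", "peak_amplitude",
      "excursion_start", "excursion_end")]
}

#' Detect spikes on a full-length continuous trace
#'
#' Same state machine as [detect_spikes()], applied to a whole recording
#' (the offline path: no trigger alignment, so no repeat detections).
#'
#' @param signal matrix `[channel, sample]` in microvolts.
#' @param sampling_rate samples per second.
#' @param config a [threshold_config()].
#' @param start_timestamp timestamp of the first column (default 0).
#' @return data.frame as in [detect_spikes()].
#' @export
detect_continuous <- function(signal, sampling_rate, config,
                              start_timestamp = 0) {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1L)
  detect_spikes(list(samples = signal, sampling_rate = sampling_rate,
                     start_timestamp = start_timestamp), config)
}

#' Extract the waveform snippet around a detected peak
#'
#' Cuts `peak - pre_ms` to `peak + post_ms` (default -0.3 ms to +1 ms)
#' out of the window. If the span exceeds the window bounds the waveform
#' is skipped (`NULL`) but the spike itself remains valid — a late- or
#' early-window spike is still counted even when its snippet cannot be
#' shown in full.
#'
#' @param spike one row of a [detect_spikes()] result (or a list with
#'   `channel` and `peak_index`).
#' @param window the `aligned_window` the spike was detected in.
#' @param pre_ms,post_ms snippet extent around the peak, milliseconds.
#' @return a `spike_waveform` (fields `channel`, `samples`,
#'   `peak_offset` — 0-based index of the peak within the snippet), or
#'   `NULL` when the snippet would leave the window.
#' @export
extract_waveform <- function(spike, window, pre_ms = 0.3, post_ms = 1.0) {
  pre <- ms_to_samples(pre_ms, window$sampling_rate)
  post <- ms_to_samples(post_ms, window$sampling_rate)
  p <- spike$peak_index
  lo <- p - pre; hi <- p + post
  if (lo < 1 || hi > ncol(window$samples)) return(NULL)
  structure(
    list(channel = spike$channel,
         samples = window$samples[spike$channel, lo:hi],
         peak_offset = pre),
    class = "spike_waveform")
}
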