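# High-level chains gluing the modules together: the online path
# (stream -> collector -> per-ROI detection -> PETH) and the offline path
# (zero-phase filter -> whole-trace detection -> tetrode merge/censor ->
# cross-correlation PETH). Both end in the same automated light-response
# criterion, which is what makes online/offline concordance measurable.

#' Run the online chain over a packet stream
#'
#' Feeds packets through a [collector()]; every trigger alignment is
#' spike-detected and accumulated into the PETH. Overlapping ROIs are
#' detected independently per event (no online deduplication).
#'
#' @param packets list of decoded packets ([replay_stream()] output), or
#'   a stream file path.
#' @param det_config a [threshold_config()].
#' @param trigger_channel digital line to align to (default 1).
#' @param roi a [roi_window()].
#' @param bin_width_ms PETH bin width (default 1 ms).
#' @return list: `peth` (accumulator), `spikes` (all per-window
#'   detections with an `event_timestamp` column), `n_windows`,
#'   `stale_events`.
#' @export
run_online <- function(packets, det_config, trigger_channel = 1,
                       roi = roi_window(), bin_width_ms = 1) {
  if (is.character(packets)) packets <- replay_stream(packets)
  first <- Find(function(p) inherits(p, "sample_packet"), packets)
  if (is.null(first)) stop("stream contains no sample packets", call. = FALSE)
  col <- collector(first$n_channels, first$sampling_rate,
                   trigger_channel = trigger_channel, roi = roi)
  acc <- peth_accumulator(first$n_channels, roi$pre_ms, roi$post_ms,
                          bin_width_ms)
  spikes <- list()
  n_windows <- 0L
  for (p in packets) {
    for (w in collector_ingest(col, p)) {
      n_windows <- n_windows + 1L
      d <- detect_spikes(w, det_config)
      acc <- peth_update(acc, d, w$event, first$sampling_rate)
      if (nrow(d)) {
        d$event_timestamp <- w$event$timestamp
        spikes[[length(spikes) + 1L]] <- d
      }
    }
  }
  spikes <- if (length(spikes)) do.call(rbind, spikes)
            else data.frame(channel = integer(), timestamp = numeric(),
                            peak_amplitude = numeric(),
                            event_timestamp = numeric())
  list(peth = acc, spikes = spikes, n_windows = n_windows,
       stale_events = col$stale_count)
}

#' Run the offline chain over a continuous recording
#'
#' Zero-phase band-pass filtering, whole-trace per-channel detection,
#' then tetrode-wide merging with largest-spike censoring — the post-hoc
#' analysis that typically recovers more unique spikes than any single
#' wire alone.
#'
#' @param signal matrix `[channel, sample]`, microvolts.
#' @param sampling_rate samples per second.
#' @param det_config a [threshold_config()].
#' @param spec a [filter_spec()] (default 600-6000 Hz Butterworth);
#'   `NULL` skips filtering (already-filtered input).
#' @param censor_ms merge censoring window (default 0.75 ms).
#' @return list: `spikes` (merged, censored detections), `per_channel`
#'   (pre-merge detections), `filtered` (the filtered signal).
#' @export
run_offline <- function(signal, sampling_rate, det_config,
                        spec = filter_spec(), censor_ms = 0.75) {
  filtered <- if (is.null(spec)) signal
              else bandpass_filter(signal, spec, sampling_rate)
  per_channel <- detect_continuous(filtered, sampling_rate, det_config)
  merged <- merge_and_censor(per_channel, censor_ms, sampling_rate)
  list(spikes = merged, per_channel = per_channel, filtered = filtered)
}

#' Offline PETH of a merged spike list against events
#'
#' Convenience wrapper around [peth_by_crosscorrelation()] producing an
#' accumulator-shaped result comparable to the online PETH.
#'
#' @param spike_timestamps spike times, samples.
#' @param event_timestamps event times, samples.
#' @param sampling_rate samples per second.
#' @param pre_ms,post_ms,bin_width_ms histogram span and resolution.
#' @return list with `counts` (1 x bins matrix), `edges`, `n_events` —
#'   accepted by [light_response_criterion()].
#' @export
offline_peth <- function(spike_timestamps, event_timestamps, sampling_rate,
                         pre_ms = 20, post_ms = 50, bin_width_ms = 1) {
  max_lag <- max(pre_ms, post_ms)
  spb <- bin_width_ms / 1000 * sampling_rate
  if (abs(spb - round(spb)) < 1e-9) {
    # bin in the integer sample domain (exact); the lag histogram is
    # unit-agnostic, so feed sample times with a sample-sized resolution
    cc <- peth_by_crosscorrelation(spike_timestamps, event_timestamps,
                                   resolution_ms = round(spb),
                                   max_lag_ms = max_lag / bin_width_ms *
                                     round(spb))
    lags <- as.numeric(names(cc)) / round(spb) * bin_width_ms
  } else {
    cc <- peth_by_crosscorrelation(spike_timestamps / sampling_rate * 1000,
                                   event_timestamps / sampling_rate * 1000,
                                   resolution_ms = bin_width_ms,
                                   max_lag_ms = max_lag)
    lags <- as.numeric(names(cc))
  }
  keep <- lags >= -pre_ms & lags < post_ms
  edges <- seq(-pre_ms, post_ms, by = bin_width_ms)
  list(counts = matrix(cc[keep], nrow = 1L), edges = edges,
       n_events = length(unique(event_timestamps)))
}
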