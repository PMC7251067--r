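# Event-aligned histogram accumulation. Bins are half-open [lo, hi) in
# milliseconds relative to the trigger, so a spike exactly at the event
# time lands in bin [0, 1) and nothing is double counted on an edge.
# Counts are raw (not rate-normalized); peth_rate() converts for display.

#' Create an empty PETH accumulator
#'
#' @param n_channels number of channels (histogram rows).
#' @param pre_ms,post_ms span of relative time covered, milliseconds; bins
#'   tile `[-pre_ms, post_ms)`.
#' @param bin_width_ms bin width, default 1 ms.
#' @return object of class `peth_accumulator`: fields `edges` (bin edges,
#'   ms), `counts` (`[channel, bin]` integer matrix), `n_events`.
#' @export
peth_accumulator <- function(n_channels, pre_ms = 20, post_ms = 50,
                             bin_width_ms = 1) {
  if (!is_count(n_channels)) stop_field("n_channels", "must be > 0")
  if (bin_width_ms <= 0) stop_field("bin_width_ms", "must be > 0")
  edges <- seq(-pre_ms, post_ms, by = bin_width_ms)
  if (length(edges) < 2L) stop_field("post_ms", "span must contain one bin")
  structure(
    list(n_channels = as.integer(n_channels),
         pre_ms = pre_ms, post_ms = post_ms, bin_width_ms = bin_width_ms,
         edges = edges,
         counts = matrix(0L, n_channels, length(edges) - 1L),
         n_events = 0L),
    class = "peth_accumulator")
}

#' Accumulate one event's spikes into a PETH
#'
#' For each spike, the relative time `r = (spike_ts - event_ts) / fs` in
#' milliseconds is binned if it falls inside `[-pre_ms, post_ms)`;
#' `n_events` is incremented exactly once per event (also when no spike
#' fell in the span, so rates stay honest).
#'
#' @param acc a [peth_accumulator()].
#' @param spikes data.frame with `channel` and `timestamp` columns
#'   ([detect_spikes()] output), timestamps on the same sample clock as
#'   the event.
#' @param event a `trigger_event`.
#' @param sampling_rate samples per second of the shared clock.
#' @return the updated accumulator.
#' @export
peth_update <- function(acc, spikes, event, sampling_rate) {
  stopifnot(inherits(acc, "peth_accumulator"), inherits(event, "trigger_event"))
  if (nrow(spikes)) {
    spb <- acc$bin_width_ms / 1000 * sampling_rate   # samples per bin
    pre_samp <- acc$pre_ms / 1000 * sampling_rate
    post_samp <- acc$post_ms / 1000 * sampling_rate
    d <- spikes$timestamp - event$timestamp
    if (all(abs(c(spb, pre_samp, post_samp) -
                round(c(spb, pre_samp, post_samp))) < 1e-9)) {
      # exact integer-sample binning (immune to float boundary wobble)
      keep <- d >= -pre_samp & d < post_samp
      bin <- (d[keep] + pre_samp) %/% spb + 1L
    } else {
      r_ms <- d / sampling_rate * 1000
      keep <- r_ms >= -acc$pre_ms & r_ms < acc$post_ms
      bin <- floor((r_ms[keep] + acc$pre_ms) / acc$bin_width_ms) + 1L
    }
    if (any(keep)) {
      ch <- spikes$channel[keep]
      for (i in seq_along(bin))
        acc$counts[ch[i], bin[i]] <- acc$counts[ch[i], bin[i]] + 1L
    }
  }
  acc$n_events <- acc$n_events + 1L
  acc
}

#' Reset an accumulator to the empty state
#'
#' Zeroes counts and the event counter; edges and configuration are kept.
#'
#' @param acc a [peth_accumulator()].
#' @return the emptied accumulator.
#' @export
peth_reset <- function(acc) {
  stopifnot(inherits(acc, "peth_accumulator"))
  acc$counts[] <- 0L
  acc$n_events <- 0L
  acc
}

#' Grouping of histogram channels for display
#'
#' Channels are collected in consecutive blocks — groups of four by
#' default, matching classical tetrode recordings; 1 to 8 channels per
#' plot accommodates single electrodes, stereotrodes and silicon probes.
#'
#' @param channels_per_plot block size, integer in 1..8 (default 4).
#' @param view `"aggregate"` (sum blocks) or `"per_channel"`.
#' @return object of class `grouping_config`.
#' @export
grouping_config <- function(channels_per_plot = 4,
                            view = c("aggregate", "per_channel")) {
  view <- match.arg(view)
  if (!is_count(channels_per_plot) || channels_per_plot > 8)
    stop_field("channels_per_plot", "must be an integer in 1..8")
  structure(list(channels_per_plot = as.integer(channels_per_plot),
                 view = view),
            class = "grouping_config")
}

#' Collapse PETH counts into channel groups
#'
#' Aggregate view sums counts over consecutive channel blocks of size
#' `channels_per_plot`; a trailing smaller block forms its own group.
#' Per-channel view returns the counts unchanged.
#'
#' @param acc a [peth_accumulator()].
#' @param grouping a [grouping_config()].
#' @return matrix `[group, bin]` of counts; `rownames` give the member
#'   channel span of each group.
#' @export
group_counts <- function(acc, grouping) {
  stopifnot(inherits(acc, "peth_accumulator"),
            inherits(grouping, "grouping_config"))
  if (grouping$view == "per_channel")
    return(acc$counts)
  g <- (seq_len(acc$n_channels) - 1L) %/% grouping$channels_per_plot + 1L
  out <- rowsum(acc$counts, g, reorder = TRUE)
  rownames(out) <- unname(vapply(split(seq_len(acc$n_channels), g),
    function(ix) if (length(ix) == 1L) as.character(ix)
                 else sprintf("%d-%d", min(ix), max(ix)), character(1)))
  out
}

#' Normalize PETH counts to firing rate
#'
#' Presentation helper: spikes per second per event.
#'
#' @param acc a [peth_accumulator()].
#' @return matrix `[channel, bin]` in spikes/s; zero matrix when no event
#'   has been accumulated yet.
#' @export
peth_rate <- function(acc) {
  stopifnot(inherits(acc, "peth_accumulator"))
  if (acc$n_events == 0L) return(acc$counts * 0)
  acc$counts / acc$n_events / (acc$bin_width_ms / 1000)
}

#' PETH via binary cross-correlation (offline variant)
#'
#' The offline formulation: both point processes are binarized at the
#' given resolution (a bin is 1 if at least one point falls in it) and the
#' lag histogram counts, for each lag, the number of (spike bin, event
#' bin) pairs at that offset. Mathematically identical to event-loop
#' accumulation whenever event times sit on the resolution grid, no two
#' events share a bin and no two spikes share a bin; TTL pulse trains and
#' refractory spiking satisfy this (see the methods vignette).
#'
#' @param spike_times_ms spike times, milliseconds on a common clock.
#' @param event_times_ms event times, same clock; must be non-empty.
#' @param resolution_ms bin width (default 1 ms).
#' @param max_lag_ms largest lag reported, in multiples of the resolution.
#' @return named integer vector of pair counts, one per lag in
#'   `-max_lag_ms .. +max_lag_ms` (names are the lag bin's lower edge).
#' @export
peth_by_crosscorrelation <- function(spike_times_ms, event_times_ms,
                                     resolution_ms = 1, max_lag_ms = 50) {
  if (!length(event_times_ms))
    stop("no events: cannot align a PETH to an empty event list",
         call. = FALSE)
  if (resolution_ms <= 0) stop_field("resolution_ms", "must be > 0")
  sb <- unique(floor(spike_times_ms / resolution_ms))
  eb <- unique(floor(event_times_ms / resolution_ms))
  nlag <- as.integer(max_lag_ms / resolution_ms)
  lags <- seq(-nlag, nlag)
  counts <- integer(length(lags))
  if (length(sb)) {
    d <- as.vector(outer(sb, eb, "-"))
    d <- d[d >= -nlag & d <= nlag]
    if (length(d)) {
      tab <- tabulate(d + nlag + 1L, nbins = length(lags))
      counts <- as.integer(tab)
    }
  }
  names(counts) <- lags * resolution_ms
  counts
}
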