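# Bounded history of the continuous stream plus pending trigger events.
# The ring buffer stores the sample with timestamp t at column
# (t mod capacity) + 1, so no read/write pointer bookkeeping is needed:
# eviction is implicit in the modular indexing, and the retrievable span is
# always the most recent min(written, capacity) samples.

#' Create a per-channel ring buffer of recent continuous history
#'
#' @param n_channels number of continuous channels.
#' @param sampling_rate samples per second.
#' @param capacity_s retained history in seconds (default 10 s, which
#'   safely covers any sensible ROI plus the 1 s raw-display span).
#' @return a mutable `ring_buffer` (environment); `append_samples()`
#'   modifies it in place.
#' @export
ring_buffer <- function(n_channels, sampling_rate = 30000, capacity_s = 10) {
  if (!is_count(n_channels)) stop_field("n_channels", "must be > 0")
  capacity <- as.integer(round(capacity_s * sampling_rate))
  if (capacity < 1L) stop_field("capacity_s", "must retain at least one sample")
  buf <- new.env(parent = emptyenv())
  buf$n_channels <- as.integer(n_channels)
  buf$sampling_rate <- sampling_rate
  buf$capacity <- capacity
  buf$data <- matrix(0, nrow = n_channels, ncol = capacity)
  buf$newest <- NA_real_   # timestamp of newest stored sample
  buf$written <- 0         # samples written (including zero-filled gaps)
  class(buf) <- "ring_buffer"
  buf
}

# write samples for consecutive timestamps ts0..ts0+n-1
rb_write <- function(buf, ts0, m) {
  n <- ncol(m)
  if (n == 0L) return(invisible(buf))
  if (n >= buf$capacity) {
    # only the tail survives
    keep <- (n - buf$capacity + 1L):n
    m <- m[, keep, drop = FALSE]
    ts0 <- ts0 + n - buf$capacity
    n <- buf$capacity
  }
  cols <- ((ts0 + seq_len(n) - 1) %% buf$capacity) + 1
  buf$data[, cols] <- m
  buf$newest <- ts0 + n - 1
  invisible(buf)
}

#' Append a sample packet to a ring buffer
#'
#' Packets must follow previously appended data; a gap (dropped packets on
#' a live stream) is zero-filled and reported with a warning so analysis
#' continues. Overlapping samples are rejected.
#'
#' @param buf a [ring_buffer()].
#' @param packet a `sample_packet` with matching channel count.
#' @return the buffer, invisibly (modified in place).
#' @export
append_samples <- function(buf, packet) {
  stopifnot(inherits(buf, "ring_buffer"), inherits(packet, "sample_packet"))
  if (packet$n_channels != buf$n_channels)
    stop(sprintf("configuration error: packet has %d channels, buffer expects %d",
                 packet$n_channels, buf$n_channels), call. = FALSE)
  ts0 <- packet$start_timestamp
  if (!is.na(buf$newest)) {
    if (ts0 <= buf$newest)
      stop(sprintf("packet at timestamp %.0f overlaps stored data (newest %.0f)",
                   ts0, buf$newest), call. = FALSE)
    gap <- ts0 - buf$newest - 1
    if (gap > 0) {
      warning(sprintf("gap of %.0f samples before timestamp %.0f: zero-filled",
                      gap, ts0), call. = FALSE)
      if (gap >= buf$capacity) {
        buf$data[] <- 0  # whole retained history falls inside the gap
        buf$newest <- ts0 - 1
      } else {
        rb_write(buf, buf$newest + 1,
                 matrix(0, nrow = buf$n_channels, ncol = gap))
      }
      buf$written <- buf$written + gap
    }
  }
  rb_write(buf, ts0, packet$samples)
  buf$written <- buf$written + packet$n_samples
  invisible(buf)
}

#' Oldest timestamp still retrievable from a ring buffer
#' @param buf a [ring_buffer()].
#' @return timestamp of the oldest retained sample, or `NA` if empty.
#' @export
oldest_timestamp <- function(buf) {
  if (is.na(buf$newest)) return(NA_real_)
  buf$newest - min(buf$written, buf$capacity) + 1
}

# contiguous slice [from_ts, from_ts + n - 1]; NULL when out of range
rb_slice <- function(buf, from_ts, n) {
  if (is.na(buf$newest)) return(NULL)
  if (from_ts < oldest_timestamp(buf) || from_ts + n - 1 > buf$newest)
    return(NULL)
  cols <- ((from_ts + seq_len(n) - 1) %% buf$capacity) + 1
  buf$data[, cols, drop = FALSE]
}

#' Define a region of interest around a trigger event
#'
#' @param pre_ms milliseconds before the event (>= 0).
#' @param post_ms milliseconds after the event (> 0).
#' @return object of class `roi_window`.
#' @export
roi_window <- function(pre_ms = 20, post_ms = 50) {
  if (!is.numeric(pre_ms) || pre_ms < 0) stop_field("pre_ms", "must be >= 0")
  if (!is.numeric(post_ms) || post_ms <= 0) stop_field("post_ms", "must be > 0")
  structure(list(pre_ms = pre_ms, post_ms = post_ms), class = "roi_window")
}

#' Extract the event-aligned window around a trigger event
#'
#' Slices `[event - pre, event + post)` out of the retained history. The
#' result carries `t0_offset`, the 0-based index of the sample at the event
#' time, so `samples[, t0_offset + 1]` is the voltage at the trigger.
#' An event whose window precedes the retained history is a "stale event":
#' the function returns `NULL` with a warning (counted by the caller, not
#' fatal) rather than aligning against evicted data.
#'
#' @param buf a [ring_buffer()].
#' @param event a `trigger_event`.
#' @param roi a [roi_window()].
#' @return an `aligned_window` (fields `event`, `samples`, `t0_offset`,
#'   `start_timestamp`, `sampling_rate`), or `NULL` for stale events.
#' @export
extract_roi <- function(buf, event, roi) {
  stopifnot(inherits(buf, "ring_buffer"), inherits(event, "trigger_event"),
            inherits(roi, "roi_window"))
  pre <- ms_to_samples(roi$pre_ms, buf$sampling_rate)
  post <- ms_to_samples(roi$post_ms, buf$sampling_rate)
  from <- event$timestamp - pre
  n <- pre + post
  if (from < 0 || (!is.na(buf$newest) && from < oldest_timestamp(buf))) {
    warning(sprintf("stale event at timestamp %.0f: window precedes retained history",
                    event$timestamp), call. = FALSE)
    return(NULL)
  }
  m <- rb_slice(buf, from, n)
  if (is.null(m))
    stop(sprintf("buffer does not yet cover event at %.0f (+%d samples)",
                 event$timestamp, post), call. = FALSE)
  structure(
    list(event = event, samples = m, t0_offset = pre,
         start_timestamp = from, sampling_rate = buf$sampling_rate),
    class = "aligned_window")
}

#' Decimate the most recent second for raw-data display
#'
#' Min/max-preserving decimation: each output bucket reports its extreme
#' value (largest magnitude, sign preserved), so brief spikes survive
#' arbitrary downsampling.
#'
#' @param buf a [ring_buffer()].
#' @param target_points number of output points per channel (>= 2).
#' @return matrix `[channel, target_points]` spanning the last second (or
#'   all stored data if less than a second is available).
#' @export
downsample_for_display <- function(buf, target_points) {
  stopifnot(inherits(buf, "ring_buffer"))
  if (!is_count(target_points) || target_points < 2)
    stop_field("target_points", "must be an integer >= 2")
  if (is.na(buf$newest)) return(matrix(0, buf$n_channels, 0))
  span <- min(buf$sampling_rate, min(buf$written, buf$capacity))
  m <- rb_slice(buf, buf$newest - span + 1, span)
  if (span <= target_points) return(m)
  bucket <- floor(seq(0, span, length.out = target_points + 1))
  out <- matrix(0, buf$n_channels, target_points)
  for (b in seq_len(target_points)) {
    seg <- m[, (bucket[b] + 1):bucket[b + 1], drop = FALSE]
    out[, b] <- seg[cbind(seq_len(nrow(seg)), max.col(abs(seg), "first"))]
  }
  out
}

#' Create a streaming collector
#'
#' Bundles the ring buffer with a pending-event queue: feed it decoded
#' packets and it returns event-aligned windows as soon as the buffer
#' covers each trigger's full ROI. Trigger events are held until data for
#' `event + post` arrives; rising edges on the configured trigger channel
#' alone cause alignment, all other events are logged and ignored.
#'
#' @param n_channels,sampling_rate,capacity_s as in [ring_buffer()].
#' @param trigger_channel digital line whose rising edges trigger PETH
#'   alignment (default 1).
#' @param roi a [roi_window()].
#' @return a mutable `collector` environment.
#' @export
collector <- function(n_channels, sampling_rate = 30000, trigger_channel = 1,
                      roi = roi_window(), capacity_s = 10) {
  col <- new.env(parent = emptyenv())
  col$buffer <- ring_buffer(n_channels, sampling_rate, capacity_s)
  col$trigger_channel <- as.integer(trigger_channel)
  col$roi <- roi
  col$pending <- list()
  col$other_events <- list()
  col$heartbeats <- 0L
  col$stale_count <- 0L
  class(col) <- "collector"
  col
}

#' Feed one packet to a collector
#'
#' @param col a [collector()].
#' @param packet a decoded packet (`sample_packet`, `trigger_event` or
#'   `heartbeat_message`).
#' @return list of `aligned_window`s that became ready (possibly empty),
#'   in event order.
#' @export
collector_ingest <- function(col, packet) {
  stopifnot(inherits(col, "collector"))
  if (inherits(packet, "heartbeat_message")) {
    col$heartbeats <- col$heartbeats + 1L
    return(list())
  }
  if (inherits(packet, "trigger_event")) {
    if (packet$edge == "rising" && packet$channel == col$trigger_channel) {
      col$pending <- c(col$pending, list(packet))
    } else {
      col$other_events <- c(col$other_events, list(packet))
    }
    return(collector_ready(col))
  }
  append_samples(col$buffer, packet)
  collector_ready(col)
}

# pop and align every pending event whose post-window is fully buffered
collector_ready <- function(col) {
  if (!length(col$pending) || is.na(col$buffer$newest)) return(list())
  post <- ms_to_samples(col$roi$post_ms, col$buffer$sampling_rate)
  out <- list()
  keep <- list()
  for (ev in col$pending) {
    if (col$buffer$newest >= ev$timestamp + post) {
      w <- withCallingHandlers(
        extract_roi(col$buffer, ev, col$roi),
        warning = function(cond) invokeRestart("muffleWarning"))
      if (is.null(w)) col$stale_count <- col$stale_count + 1L
      else out <- c(out, list(w))
    } else {
      keep <- c(keep, list(ev))
    }
  }
  col$pending <- keep
  out
}
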