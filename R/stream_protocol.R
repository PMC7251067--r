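# Wire format ("opeth-jsonl/1"): one JSON object per line. Continuous
# data packets carry a base64 payload of little-endian float32 microvolt
# samples, channel-major (all of channel 1, then channel 2, ...). Digital
# events and heartbeats are plain JSON. All computation runs transport-free
# from files; a live socket adapter only needs to produce the same lines.

PROTOCOL_VERSION <- "opeth-jsonl/1"

#' Construct a block of continuous multichannel samples
#'
#' The streaming unit: a timestamped block of voltage samples. Timestamps
#' are 0-based integer sample counts since acquisition start, so the packet
#' covers samples `start_timestamp` to `start_timestamp + n_samples - 1` on
#' a single clock shared with digital events.
#'
#' @param start_timestamp 0-based sample index of the first sample.
#' @param samples numeric matrix, microvolts, `[channel, sample]`.
#' @param sampling_rate samples per second (default 30000).
#' @return object of class `sample_packet`.
#' @export
sample_packet <- function(start_timestamp, samples, sampling_rate = 30000) {
  if (!is.matrix(samples)) samples <- matrix(samples, nrow = 1L)
  if (!is.numeric(start_timestamp) || length(start_timestamp) != 1L ||
      is.na(start_timestamp) || start_timestamp < 0 ||
      start_timestamp != trunc(start_timestamp))
    stop_field("start_timestamp", "must be a non-negative integer sample index")
  if (!is_count(sampling_rate))
    stop_field("sampling_rate", "must be > 0")
  structure(
    list(start_timestamp = as.numeric(start_timestamp),
         n_channels = nrow(samples),
         n_samples = ncol(samples),
         sampling_rate = as.numeric(sampling_rate),
         samples = samples),
    class = "sample_packet")
}

#' Construct a digital (TTL) event
#'
#' @param channel small integer id of the digital line (1-based).
#' @param timestamp 0-based sample index of the edge.
#' @param edge `"rising"` or `"falling"`; only rising edges trigger PETH
#'   alignment downstream.
#' @return object of class `trigger_event`.
#' @export
trigger_event <- function(channel, timestamp, edge = c("rising", "falling")) {
  edge <- match.arg(edge)
  if (!is_count(channel)) stop_field("channel", "must be a positive integer")
  if (!is.numeric(timestamp) || length(timestamp) != 1L || is.na(timestamp) ||
      timestamp < 0 || timestamp != trunc(timestamp))
    stop_field("timestamp", "must be a non-negative integer sample index")
  structure(
    list(channel = as.integer(channel),
         timestamp = as.numeric(timestamp),
         edge = edge),
    class = "trigger_event")
}

#' Construct a heartbeat message
#'
#' Heartbeats let a live acquisition plugin track connected clients. In
#' file replay they are decoded and logged but carry no data; the interval
#' and timeout are deployment configuration, not asserted by this package.
#'
#' @param client_id non-empty string identifying the client.
#' @param sent_at wall-clock send time (POSIXct or numeric seconds).
#' @return object of class `heartbeat_message`.
#' @export
heartbeat_message <- function(client_id, sent_at = Sys.time()) {
  if (!is.character(client_id) || length(client_id) != 1L || !nzchar(client_id))
    stop_field("client_id", "must be a non-empty string")
  structure(
    list(client_id = client_id, sent_at = as.numeric(sent_at)),
    class = "heartbeat_message")
}

# float32 payload codec ------------------------------------------------

encode_f32 <- function(m) {
  # channel-major: concatenate rows
  raw <- writeBin(as.numeric(t(m)), raw(), size = 4L, endian = "little")
  jsonlite::base64_enc(raw)
}

decode_f32 <- function(b64, n_channels, n_samples) {
  raw <- jsonlite::base64_dec(b64)
  if (length(raw) != 4L * n_channels * n_samples)
    stop("schema error: payload length does not match n_channels * n_samples",
         call. = FALSE)
  v <- readBin(raw, numeric(), n = n_channels * n_samples, size = 4L,
               endian = "little")
  matrix(v, nrow = n_channels, byrow = TRUE)
}

#' Encode a packet as one JSON line
#'
#' Self-describing envelope with fields `version`, `type`
#' (`"samples"`, `"event"` or `"heartbeat"`), the metadata the acquisition
#' side broadcasts (timestamp, event channel, number of data channels,
#' sample count, sampling rate) and, for sample packets, a base64
#' float32 payload. `decode_packet(encode_packet(p))` reproduces `p`
#' field-for-field; voltages round-trip at float32 precision, which is the
#' recording precision.
#'
#' @param packet a `sample_packet`, `trigger_event` or `heartbeat_message`.
#' @return a single-element character vector (one JSON line, no newline).
#' @export
encode_packet <- function(packet) {
  if (inherits(packet, "sample_packet")) {
    if (!identical(dim(packet$samples),
                   c(packet$n_channels, packet$n_samples)))
      stop_field("samples", "matrix dimensions must equal (n_channels, n_samples)")
    obj <- list(version = PROTOCOL_VERSION, type = "samples",
                timestamp = packet$start_timestamp,
                n_channels = packet$n_channels,
                n_samples = packet$n_samples,
                sampling_rate = packet$sampling_rate,
                content = encode_f32(packet$samples))
  } else if (inherits(packet, "trigger_event")) {
    obj <- list(version = PROTOCOL_VERSION, type = "event",
                event_channel = packet$channel,
                timestamp = packet$timestamp,
                edge = packet$edge)
  } else if (inherits(packet, "heartbeat_message")) {
    obj <- list(version = PROTOCOL_VERSION, type = "heartbeat",
                client_id = packet$client_id,
                sent_at = packet$sent_at)
  } else {
    stop("encode_packet: unsupported object of class ",
         paste(class(packet), collapse = "/"), call. = FALSE)
  }
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
}

#' Decode one JSON line into a typed packet
#'
#' Unknown type tags are reported (with the offending tag), never silently
#' dropped; missing mandatory fields raise a schema error naming the field.
#'
#' @param message a single JSON line as produced by [encode_packet()].
#' @return a `sample_packet`, `trigger_event` or `heartbeat_message`.
#' @export
decode_packet <- function(message) {
  obj <- tryCatch(jsonlite::fromJSON(message, simplifyVector = TRUE),
                  error = function(e)
                    stop("parse error: malformed JSON envelope: ",
                         conditionMessage(e), call. = FALSE))
  need <- function(fields) {
    miss <- setdiff(fields, names(obj))
    if (length(miss))
      stop("schema error: missing mandatory field(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  need("type")
  switch(
    as.character(obj$type),
    samples = {
      need(c("timestamp", "n_channels", "n_samples", "sampling_rate",
             "content"))
      sample_packet(obj$timestamp,
                    decode_f32(obj$content, obj$n_channels, obj$n_samples),
                    obj$sampling_rate)
    },
    event = {
      need(c("event_channel", "timestamp", "edge"))
      trigger_event(obj$event_channel, obj$timestamp, obj$edge)
    },
    heartbeat = {
      need(c("client_id", "sent_at"))
      heartbeat_message(obj$client_id, obj$sent_at)
    },
    stop("unknown packet type: '", obj$type, "'", call. = FALSE)
  )
}

#' Replay a JSON-lines stream file
#'
#' Reads one message per line, in file order. Out-of-order sample
#' timestamps are tolerated (a live stream can drop or reorder packets):
#' a warning is emitted and replay continues.
#'
#' @param path path to a JSON-lines stream file.
#' @param speed `"max"` replays as fast as possible; `"realtime"` sleeps
#'   between sample packets to pace the replay at the recording rate.
#' @return a list of decoded packets, in file order.
#' @export
replay_stream <- function(path, speed = c("max", "realtime")) {
  speed <- match.arg(speed)
  if (!file.exists(path)) stop("stream file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  packets <- lapply(lines, decode_packet)
  last_ts <- -Inf
  for (p in packets) {
    if (inherits(p, "sample_packet")) {
      if (p$start_timestamp < last_ts)
        warning(sprintf(
          "out-of-order sample packet at timestamp %.0f (previous end %.0f); continuing",
          p$start_timestamp, last_ts), call. = FALSE)
      last_ts <- max(last_ts, p$start_timestamp + p$n_samples)
      if (speed == "realtime")
        Sys.sleep(p$n_samples / p$sampling_rate)
    }
  }
  packets
}
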