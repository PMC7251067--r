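# Shared helpers. Millisecond-to-sample conversion is done once per
# boundary with round-half-away-from-zero, never cumulatively, so ROI and
# waveform lengths cannot drift by one sample across calls.

#' Convert milliseconds to a whole number of samples
#'
#' Uses round-half-away-from-zero (0.5 -> 1, -0.5 -> -1), applied once per
#' boundary. `round()` in R rounds half to even, which would make window
#' lengths depend on parity of the tie; a fixed tie direction keeps every
#' (pre, post, fs) combination reproducible.
#'
#' @param ms time in milliseconds (scalar or vector).
#' @param sampling_rate samples per second.
#' @return integer-valued numeric vector of sample counts.
#' @export
ms_to_samples <- function(ms, sampling_rate) {
  x <- ms / 1000 * sampling_rate
  trunc(x + 0.5 * sign(x))
}

#' @keywords internal
#' @noRd
stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

#' @keywords internal
#' @noRd
is_count <- function(x, positive = TRUE) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == trunc(x) &&
    (if (positive) x > 0 else x >= 0)
}
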