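# Offline raw-recording interchange: interleaved little-endian int16
# samples plus a JSON metadata sidecar ("<path>.json") carrying
# n_channels, sampling_rate and the microvolts-per-bit scale.

#' Write a recording as raw int16 binary with a JSON sidecar
#'
#' Samples are interleaved channel-fastest (frame by frame), little
#' endian, with voltages divided by `scale_uv_per_bit` and clamped to the
#' int16 range. The sidecar `<path>.json` documents `n_channels`,
#' `sampling_rate` and `scale_uv_per_bit`.
#'
#' @param signal matrix `[channel, sample]`, microvolts.
#' @param path output file (sidecar written next to it).
#' @param sampling_rate samples per second.
#' @param scale_uv_per_bit microvolts per integer step (default 0.195,
#'   a common amplifier resolution).
#' @return `path`, invisibly.
#' @export
write_raw_binary <- function(signal, path, sampling_rate = 30000,
                             scale_uv_per_bit = 0.195) {
  if (!is.matrix(signal)) signal <- matrix(signal, nrow = 1L)
  q <- as.integer(pmax(pmin(round(signal / scale_uv_per_bit),
                            32767), -32768))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(as.vector(q), con, size = 2L, endian = "little")
  jsonlite::write_json(
    list(n_channels = nrow(signal), sampling_rate = sampling_rate,
         scale_uv_per_bit = scale_uv_per_bit),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a raw int16 binary recording and its JSON sidecar
#'
#' @param path file written by [write_raw_binary()] (or any int16
#'   interleaved recording with a matching sidecar).
#' @return list: `signal` (`[channel, sample]`, microvolts),
#'   `sampling_rate`, `scale_uv_per_bit`.
#' @export
read_raw_binary <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(path)) stop("raw file not found: ", path, call. = FALSE)
  if (!file.exists(meta_path))
    stop("metadata sidecar not found: ", meta_path, call. = FALSE)
  meta <- jsonlite::fromJSON(meta_path)
  n_bytes <- file.info(path)$size
  v <- readBin(path, integer(), n = n_bytes / 2, size = 2L,
               endian = "little")
  if (length(v) %% meta$n_channels != 0)
    stop("raw file length is not a multiple of n_channels", call. = FALSE)
  list(signal = matrix(v * meta$scale_uv_per_bit, nrow = meta$n_channels),
       sampling_rate = meta$sampling_rate,
       scale_uv_per_bit = meta$scale_uv_per_bit)
}
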