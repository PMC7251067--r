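# Zero-phase Butterworth band-pass filtering for the offline chain.
# No DSP package is assumed: the design is the textbook one — analog
# Butterworth prototype poles, low-pass-to-band-pass transform with
# prewarped edge frequencies, bilinear transform — and zero phase comes
# from filtering forward and backward (effective order 2x, magnitude
# squared, no phase shift). Coefficients match SciPy's butter() to within
# float rounding; tests check the analytic magnitude response instead of
# frozen coefficients.

#' Band-pass filter specification
#'
#' Defaults are the conventional spike band: 600-6000 Hz, 4th-order
#' Butterworth, applied forward-backward (non-causal, zero phase) — the
#' offline luxury that a causal online filter cannot afford.
#'
#' @param low_cut,high_cut band edges in Hz; must satisfy
#'   `0 < low_cut < high_cut < fs/2` for the sampling rate used.
#' @param order filter order of the one-directional design (default 4;
#'   forward-backward application doubles the effective order).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(low_cut = 600, high_cut = 6000, order = 4) {
  if (!is.numeric(low_cut) || low_cut <= 0)
    stop_field("low_cut", "must be > 0")
  if (!is.numeric(high_cut) || high_cut <= low_cut)
    stop_field("high_cut", "must exceed low_cut")
  if (!is_count(order)) stop_field("order", "must be a positive integer")
  structure(list(low_cut = low_cut, high_cut = high_cut,
                 family = "butterworth", order = as.integer(order),
                 phase = "zero"),
            class = "filter_spec")
}

poly_from_roots <- function(roots) {
  p <- 1 + 0i
  for (r in roots) p <- c(p, 0i) - r * c(0i, p)
  p
}

#' Digital Butterworth band-pass coefficients
#'
#' @param spec a [filter_spec()].
#' @param fs sampling rate, Hz.
#' @return list with numerator `b` and denominator `a` (length
#'   `2 * order + 1` each, `a[1] == 1`).
#' @export
butter_bandpass <- function(spec, fs) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$high_cut >= fs / 2)
    stop_field("high_cut", "cutoffs must lie inside (0, fs/2)")
  n <- spec$order
  fs2 <- 2 * fs
  # prewarped analog band edges
  wl <- fs2 * tan(pi * spec$low_cut / fs)
  wh <- fs2 * tan(pi * spec$high_cut / fs)
  w0sq <- wl * wh
  bw <- wh - wl
  # analog low-pass prototype (unit cutoff): poles on the left unit circle
  k <- seq_len(n)
  proto <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  # low-pass -> band-pass: each pole splits in two; n zeros appear at s = 0
  half <- proto * bw / 2
  p_bp <- c(half + sqrt(half^2 - w0sq), half - sqrt(half^2 - w0sq))
  gain_bp <- bw^n
  # bilinear transform s -> 2fs (z-1)/(z+1)
  zd <- (fs2 + p_bp) / (fs2 - p_bp)
  # n analog zeros at 0 map to z = 1; the n zeros at infinity map to z = -1
  zz <- c(rep(1 + 0i, n), rep(-1 + 0i, n))
  kd <- gain_bp * Re(fs2^n / prod(fs2 - p_bp))
  b <- Re(kd * poly_from_roots(zz))
  a <- Re(poly_from_roots(zd))
  list(b = b, a = a / a[1])
}

# single-pass IIR: FIR part by convolution, AR part recursively
iir_apply <- function(b, a, x) {
  nb <- length(b)
  xp <- c(rep(0, nb - 1), x)
  v <- stats::filter(xp, b, method = "convolution", sides = 1)
  v <- as.numeric(v)[nb:(nb - 1 + length(x))]
  if (length(a) > 1L)
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  v
}

# forward-backward filtering with odd-reflection padding; pad length is
# chosen from the slowest pole so edge transients decay below 1e-8
filtfilt_fb <- function(b, a, x) {
  n <- length(x)
  rmax <- max(Mod(polyroot(rev(a))))
  rmax <- min(rmax, 1 - 1e-9)
  npad <- min(n - 1L, max(3L * (length(a) - 1L),
                          ceiling(log(1e-8) / log(rmax))))
  front <- 2 * x[1] - x[seq(npad + 1, 2)]
  back <- 2 * x[n] - x[seq(n - 1, n - npad)]
  y <- iir_apply(b, a, c(front, x, back))
  y <- rev(iir_apply(b, a, rev(y)))
  y[(npad + 1):(npad + n)]
}

#' Zero-phase band-pass filter a continuous trace
#'
#' Applies the Butterworth design of `spec` forward and backward
#' (non-causal): the output has exactly zero phase shift and the squared
#' magnitude response of the one-directional filter, at equal length.
#'
#' @param signal numeric vector or `[channel, sample]` matrix, microvolts.
#' @param spec a [filter_spec()].
#' @param fs sampling rate, Hz.
#' @return filtered trace, same shape as `signal`.
#' @export
bandpass_filter <- function(signal, spec = filter_spec(), fs) {
  coefs <- butter_bandpass(spec, fs)
  if (is.matrix(signal)) {
    out <- signal
    for (ch in seq_len(nrow(signal)))
      out[ch, ] <- filtfilt_fb(coefs$b, coefs$a, signal[ch, ])
    out
  } else {
    filtfilt_fb(coefs$b, coefs$a, signal)
  }
}

#' Magnitude response of the zero-phase band-pass design
#'
#' Analytic check value: the forward-backward Butterworth band-pass gain
#' at frequency `f` is `1 / (1 + ((W^2 - W0^2) / (B W))^(2n))` with
#' prewarped analog frequencies, i.e. the squared magnitude of the
#' one-directional filter. Used as the independent oracle for
#' [bandpass_filter()].
#'
#' @param spec a [filter_spec()].
#' @param fs sampling rate, Hz.
#' @param f frequencies at which to evaluate, Hz.
#' @return gain (amplitude ratio) of the zero-phase application at `f`.
#' @export
bandpass_gain <- function(spec, fs, f) {
  fs2 <- 2 * fs
  wl <- fs2 * tan(pi * spec$low_cut / fs)
  wh <- fs2 * tan(pi * spec$high_cut / fs)
  w <- fs2 * tan(pi * f / fs)
  ratio <- (w^2 - wl * wh) / ((wh - wl) * w)
  1 / (1 + ratio^(2 * spec$order))
}
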