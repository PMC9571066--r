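#' Band-pass filter specification
#'
#' @param low_hz lower band edge in Hz.
#' @param high_hz upper band edge in Hz.
#' @param fs sampling rate in Hz; band edges must lie below Nyquist.
#' @return an object of class `bandpass_spec`.
#' @export
bandpass_spec <- function(low_hz = 80, high_hz = 500, fs = 5000) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    stop("band edges must satisfy 0 < low_hz < high_hz < fs/2", call. = FALSE)
  }
  structure(list(low_hz = low_hz, high_hz = high_hz, fs = fs),
            class = "bandpass_spec")
}

# Hamming-windowed sinc band-pass kernel. Transition width ~20 Hz at 5 kHz
# (scaled with fs), which keeps stopband attenuation >= ~50 dB one octave
# outside the band while the passband gain stays within 1 dB.
fir_bandpass_kernel <- function(low_hz, high_hz, fs, transition_hz = 20 * fs / 5000) {
  ntaps <- as.integer(ceiling(3.3 * fs / transition_hz))
  if (ntaps %% 2L == 0L) ntaps <- ntaps + 1L
  m <- (ntaps - 1L) / 2L
  nn <- seq.int(-m, m)
  sinc <- function(fc) {
    h <- 2 * fc / fs * rep(1, length(nn))
    nz <- nn != 0L
    h[nz] <- sin(2 * pi * fc * nn[nz] / fs) / (pi * nn[nz])
    h
  }
  h <- sinc(high_hz) - sinc(low_hz)
  w <- 0.54 + 0.46 * cos(pi * nn / m)  # Hamming
  h * w
}

# FFT convolution, "same" alignment for an odd symmetric kernel -> zero
# phase. Signal is padded with zeros; pad length chosen 2-3-5 smooth so
# stats::fft stays fast for awkward lengths.
fft_convolve_same <- function(v, h) {
  n <- length(v)
  L <- length(h)
  m <- stats::nextn(n + L - 1L, c(2, 3, 5))
  vv <- c(v, numeric(m - n))
  hh <- c(h, numeric(m - L))
  out <- Re(stats::fft(stats::fft(vv) * stats::fft(hh), inverse = TRUE)) / m
  r <- (L - 1L) / 2L
  out[(r + 1L):(r + n)]
}

#' Zero-phase band-pass filter
#'
#' Applies a linear-phase FIR band-pass (Hamming-windowed sinc) with the
#' group delay compensated, so event timing stays aligned with the raw
#' trace. Note that sharp transients (interictal spikes) passed through
#' this filter ring: the output oscillates within the passband, which is
#' precisely the mechanism that turns spikes into false ripple detections.
#'
#' @param x a [signal1d()].
#' @param spec a [bandpass_spec()]; its `fs` must match `x$fs`.
#' @return a filtered [signal1d()] of the same length.
#' @export
bandpass <- function(x, spec = bandpass_spec(fs = x$fs)) {
  x <- as_signal1d(x)
  if (!inherits(spec, "bandpass_spec")) stop("`spec` must be a bandpass_spec", call. = FALSE)
  if (abs(spec$fs - x$fs) > 1e-9) stop("bandpass_spec fs does not match signal fs", call. = FALSE)
  h <- fir_bandpass_kernel(spec$low_hz, spec$high_hz, spec$fs)
  if (length(x$samples) < length(h)) {
    stop(sprintf("signal too short for the band-pass filter (need >= %d samples)",
                 length(h)), call. = FALSE)
  }
  signal1d(fft_convolve_same(x$samples, h), x$fs)
}

#' Full-wave rectification
#'
#' @param x a [signal1d()].
#' @return elementwise absolute value, as a [signal1d()].
#' @export
rectify <- function(x) {
  x <- as_signal1d(x)
  signal1d(abs(x$samples), x$fs)
}

#' Rectified first difference
#'
#' `|diff(x)|`, right-padded with its final value so the output keeps the
#' input length and downstream centred windows stay aligned with raw
#' sample indices.
#'
#' @param x a [signal1d()] of length >= 2.
#' @return a [signal1d()] of the same length.
#' @export
rectified_first_difference <- function(x) {
  x <- as_signal1d(x)
  if (length(x$samples) < 2L) stop("need at least 2 samples for a first difference", call. = FALSE)
  d <- abs(diff(x$samples))
  signal1d(c(d, d[length(d)]), x$fs)
}

# Centred windowed mean of `v` (odd window k), edge-replicated, via cumsum.
running_mean <- function(v, k) {
  r <- (k - 1L) %/% 2L
  if (r == 0L) return(v)
  n <- length(v)
  padded <- c(rep(v[1L], r), v, rep(v[n], r))
  cs <- cumsum(padded)
  (cs[(k):(n + k - 1L)] - c(0, cs[1:(n - 1L)])) / k
}

#' Centred moving average
#'
#' Mean over a centred odd-sample window (converted from milliseconds as in
#' [struct_window()]), with edge samples replicated.
#'
#' @param x a [signal1d()].
#' @param window_ms window length in milliseconds.
#' @return a smoothed [signal1d()] of the same length.
#' @export
moving_average <- function(x, window_ms) {
  x <- as_signal1d(x)
  k <- ms_to_samples_odd(window_ms, x$fs)
  signal1d(running_mean(x$samples, k), x$fs)
}

#' Moving RMS envelope
#'
#' Root-mean-square over a centred odd-sample window, edge-replicated.
#'
#' @param x a [signal1d()].
#' @param window_ms window length in milliseconds (3 ms is the
#'   conventional choice for ripple detection).
#' @return a [signal1d()] of the same length.
#' @export
rms_envelope <- function(x, window_ms = 3) {
  x <- as_signal1d(x)
  k <- ms_to_samples_odd(window_ms, x$fs)
  signal1d(sqrt(pmax(running_mean(x$samples^2, k), 0)), x$fs)
}
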