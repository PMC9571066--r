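#' Single-channel sampled signal
#'
#' Lightweight container pairing a numeric sample vector with its sampling
#' rate. All processing functions in the package consume and return
#' `signal1d` objects so that window sizes given in milliseconds can be
#' converted to sample counts unambiguously.
#'
#' @param samples numeric vector of amplitudes (typically microvolts).
#' @param fs sampling rate in Hz (positive scalar).
#' @return an object of class `signal1d`: a list with elements `samples`
#'   and `fs`.
#' @examples
#' x <- signal1d(sin(2 * pi * 10 * seq(0, 1, by = 1 / 500)), fs = 500)
#' length(x)
#' @export
signal1d <- function(samples, fs) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    stop("`samples` must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(samples)) stop("`samples` must not contain missing values", call. = FALSE)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    stop("`fs` must be a positive finite scalar (Hz)", call. = FALSE)
  }
  structure(list(samples = as.numeric(samples), fs = as.numeric(fs)),
            class = "signal1d")
}

#' @export
length.signal1d <- function(x) length(x$samples)

#' @export
print.signal1d <- function(x, ...) {
  cat(sprintf("<signal1d: %d samples @ %g Hz (%.3f s)>\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

as_signal1d <- function(x, fs = NULL) {
  if (inherits(x, "signal1d")) return(x)
  if (is.null(fs)) stop("`fs` required when `x` is a plain numeric vector", call. = FALSE)
  signal1d(x, fs)
}

#' Convert a window length in milliseconds to an odd sample count
#'
#' Windows are centred and symmetric, so the sample count is the nearest odd
#' integer to `width_ms * fs / 1000`, with ties rounded upwards. 1 ms at
#' 5 kHz gives 5 samples; 0.8 ms at 5 kHz (4 samples, equidistant from 3
#' and 5) gives 5.
#'
#' @param width_ms window length in milliseconds (positive scalar).
#' @param fs sampling rate in Hz.
#' @return odd positive integer sample count.
#' @export
ms_to_samples_odd <- function(width_ms, fs) {
  if (!is.numeric(width_ms) || length(width_ms) != 1L || !is.finite(width_ms) ||
      width_ms <= 0) {
    stop("`width_ms` must be a positive finite scalar", call. = FALSE)
  }
  m <- width_ms * fs / 1000
  if (m <= 1) return(1L)
  lower <- 2L * as.integer(floor((m - 1) / 2)) + 1L  # largest odd <= m (or m-1 if m odd+eps)
  upper <- lower + 2L
  if ((m - lower) < (upper - m)) lower else upper
}

#' Structuring window for morphological operators
#'
#' A flat (zero-height) structuring element described by its width. The
#' width in samples is derived from the width in milliseconds via
#' [ms_to_samples_odd()] so that the element is symmetric about the centre
#' sample.
#'
#' @param width_ms window width in milliseconds.
#' @param fs sampling rate in Hz of the signals the window will be applied
#'   to.
#' @return an object of class `struct_window` with fields `width_ms` and
#'   `width_samples`.
#' @export
struct_window <- function(width_ms, fs) {
  k <- ms_to_samples_odd(width_ms, fs)
  structure(list(width_ms = as.numeric(width_ms), width_samples = k),
            class = "struct_window")
}

#' @export
print.struct_window <- function(x, ...) {
  cat(sprintf("<struct_window: %g ms = %d samples>\n", x$width_ms, x$width_samples))
  invisible(x)
}

# Accept either a struct_window or a raw odd sample count.
window_samples <- function(w, x) {
  if (inherits(w, "struct_window")) {
    k <- w$width_samples
  } else if (is.numeric(w) && length(w) == 1L && is.finite(w)) {
    k <- as.integer(w)
    if (k < 1L) stop("window must be a positive number of samples", call. = FALSE)
    if (k %% 2L == 0L) stop("window sample count must be odd (centred window)", call. = FALSE)
  } else {
    stop("`w` must be a struct_window or an odd positive integer", call. = FALSE)
  }
  if (k > 2L * length(x$samples) - 1L) {
    stop("structuring window wider than the edge-padded signal", call. = FALSE)
  }
  k
}
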