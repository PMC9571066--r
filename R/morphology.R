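#' One-dimensional flat grayscale morphology
#'
#' Erosion and dilation of a sampled signal under a flat (zero-height)
#' symmetric structuring element are exact centred sliding minima and
#' maxima; opening and closing are their compositions. Edge samples are
#' replicated outside the signal domain, which for order statistics is the
#' same as clamping the window to the domain. The fast path is an O(n)
#' monotonic-wedge implementation in C++ (equivalent to the van Herk block
#' algorithm); [brute_force_extremum()] provides the O(n*w) reference
#' semantics used as a testing oracle.
#'
#' @param x a [signal1d()].
#' @param w a [struct_window()], or an odd positive integer sample count.
#' @return a [signal1d()] of the same length and sampling rate.
#' @seealso [morph_open()], [morph_close()], [brute_force_extremum()]
#' @examples
#' x <- signal1d(c(1, 3, 2, 5, 0), fs = 1000)
#' erode(x, 3)$samples   # c(1, 1, 2, 0, 0)
#' dilate(x, 3)$samples  # c(3, 3, 5, 5, 5)
#' @name morphology
NULL

#' @rdname morphology
#' @export
erode <- function(x, w) {
  x <- as_signal1d(x)
  k <- window_samples(w, x)
  signal1d(sliding_extremum_cpp(x$samples, k, FALSE), x$fs)
}

#' @rdname morphology
#' @export
dilate <- function(x, w) {
  x <- as_signal1d(x)
  k <- window_samples(w, x)
  signal1d(sliding_extremum_cpp(x$samples, k, TRUE), x$fs)
}

#' Morphological opening (erosion, then dilation)
#'
#' Opening truncates peaks narrower than the structuring window down to the
#' level at which they are at least as wide as the window; it is
#' anti-extensive (`open(x) <= x` pointwise) and idempotent.
#'
#' @inheritParams morphology
#' @return a [signal1d()].
#' @export
morph_open <- function(x, w) dilate(erode(x, w), w)

#' Morphological closing (dilation, then erosion)
#'
#' Closing fills valleys narrower than the structuring window; it is
#' extensive (`close(x) >= x` pointwise) and idempotent.
#'
#' @inheritParams morphology
#' @return a [signal1d()].
#' @export
morph_close <- function(x, w) erode(dilate(x, w), w)

#' Naive sliding extremum (testing oracle)
#'
#' Reference O(n*w) implementation of the centred sliding minimum/maximum
#' with edge replication. Defined as the reference semantics against which
#' the fast C++ path must agree exactly (these are order statistics, so no
#' numerical tolerance applies).
#'
#' @inheritParams morphology
#' @param mode `"min"` or `"max"`.
#' @return a [signal1d()].
#' @export
brute_force_extremum <- function(x, w, mode = c("min", "max")) {
  mode <- match.arg(mode)
  x <- as_signal1d(x)
  k <- window_samples(w, x)
  r <- (k - 1L) %/% 2L
  v <- x$samples
  n <- length(v)
  f <- if (mode == "min") min else max
  out <- vapply(seq_len(n), function(i) {
    f(v[max(1L, i - r):min(n, i + r)])
  }, numeric(1))
  signal1d(out, x$fs)
}
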