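#' Parameters of the RMS ripple detector
#'
#' Defaults follow the classical RMS ripple detector: 80-500 Hz band-pass,
#' RMS in a 3 ms moving window, candidate runs above mean + 5 SD of the
#' baseline RMS lasting at least 6 ms, runs separated by less than 10 ms
#' clustered together, and confirmation by at least 6 rectified peaks above
#' mean + 3 SD of the rectified band-passed baseline.
#'
#' @param band a [bandpass_spec()].
#' @param rms_window_ms RMS envelope window (ms).
#' @param candidate_sd SD multiplier for the candidate RMS threshold.
#' @param min_duration_ms minimum event duration (ms), applied after
#'   merging.
#' @param merge_gap_ms runs separated by less than this gap (ms) are merged.
#' @param peak_sd SD multiplier for the confirmation peak threshold.
#' @param min_peaks minimum number of qualifying rectified peaks.
#' @return an object of class `detector_params`.
#' @export
detector_params <- function(band = bandpass_spec(80, 500, fs = 5000),
                            rms_window_ms = 3, candidate_sd = 5,
                            min_duration_ms = 6, merge_gap_ms = 10,
                            peak_sd = 3, min_peaks = 6L) {
  stopifnot(rms_window_ms > 0, candidate_sd > 0, min_duration_ms > 0,
            merge_gap_ms > 0, peak_sd > 0, min_peaks >= 1)
  structure(list(band = band, rms_window_ms = rms_window_ms,
                 candidate_sd = candidate_sd, min_duration_ms = min_duration_ms,
                 merge_gap_ms = merge_gap_ms, peak_sd = peak_sd,
                 min_peaks = as.integer(min_peaks)),
            class = "detector_params")
}

# Maximal runs of TRUE in a logical vector, as 0-based half-open intervals.
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

# Threshold-run extraction shared by the detector: strict threshold
# crossings, merge runs closer than merge_gap_ms, then apply the minimum
# duration (merging deliberately precedes the duration test, so two short
# bursts close together can form one valid event).
threshold_runs <- function(values, thr, fs, min_duration_ms, merge_gap_ms) {
  runs <- logical_runs(values > thr)
  if (nrow(runs) == 0L) return(runs)
  gap_samples <- merge_gap_ms * fs / 1000
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) {
    for (i in 2:nrow(runs)) {
      last <- nrow(merged)
      if (runs[i, "start"] - merged[last, "end"] < gap_samples) {
        merged[last, "end"] <- runs[i, "end"]
      } else {
        merged <- rbind(merged, runs[i, , drop = FALSE])
      }
    }
  }
  dur_ms <- (merged[, "end"] - merged[, "start"]) / fs * 1000
  merged[dur_ms >= min_duration_ms, , drop = FALSE]
}

# Indices (1-based) of local maxima; samples strictly greater than both
# neighbours, with plateaus contributing their centre once. Endpoints are
# not maxima.
local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer())
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  m <- length(r$values)
  if (m < 3L) return(integer())
  idx <- which(r$values[2:(m - 1L)] > r$values[1:(m - 2L)] &
                 r$values[2:(m - 1L)] > r$values[3:m]) + 1L
  as.integer(floor((starts[idx] + ends[idx]) / 2))
}

baseline_values <- function(v, baseline) {
  if (is.null(baseline)) return(v)
  stopifnot(length(baseline) == 2L, baseline[1] >= 0, baseline[2] > baseline[1],
            baseline[2] <= length(v))
  v[(baseline[1] + 1L):baseline[2]]
}

#' Candidate ripple events from the RMS envelope
#'
#' Band-passes the signal, computes its moving RMS envelope and returns the
#' maximal runs where the envelope strictly exceeds `mean + candidate_sd *
#' SD` of the baseline RMS trace. Runs separated by less than
#' `merge_gap_ms` are merged, and the minimum duration is enforced after
#' merging. By default the baseline is the whole analysed segment; pass
#' `baseline = c(start, end)` (0-based half-open samples) to use an
#' event-free epoch instead.
#'
#' @param x a [signal1d()].
#' @param p a [detector_params()].
#' @param baseline optional 0-based half-open sample interval for baseline
#'   statistics.
#' @return an [event_table()] of unlabeled candidates (score = peak RMS).
#' @export
detect_candidates <- function(x, p = detector_params(band = bandpass_spec(fs = x$fs)),
                              baseline = NULL) {
  x <- as_signal1d(x)
  rms <- rms_envelope(bandpass(x, p$band), p$rms_window_ms)$samples
  base <- baseline_values(rms, baseline)
  s <- stats::sd(base)
  if (!is.finite(s) || s == 0) return(event_table())
  thr <- mean(base) + p$candidate_sd * s
  runs <- threshold_runs(rms, thr, x$fs, p$min_duration_ms, p$merge_gap_ms)
  if (nrow(runs) == 0L) return(event_table())
  score <- vapply(seq_len(nrow(runs)), function(i) {
    max(rms[(runs[i, "start"] + 1L):runs[i, "end"]])
  }, numeric(1))
  event_table(runs[, "start"], runs[, "end"], "unlabeled", score)
}

#' Confirm a candidate event as an oscillation
#'
#' A candidate is confirmed when the rectified band-passed segment contains
#' at least `min_peaks` local maxima strictly above `mean + peak_sd * SD`
#' of the rectified band-passed baseline.
#'
#' @param x_filtered the band-passed [signal1d()] (not yet rectified).
#' @param start_sample,end_sample 0-based half-open event bounds.
#' @param p a [detector_params()].
#' @param baseline optional baseline interval as in [detect_candidates()].
#' @return logical scalar.
#' @export
confirm_hfo <- function(x_filtered, start_sample, end_sample,
                        p = detector_params(), baseline = NULL) {
  x_filtered <- as_signal1d(x_filtered)
  n <- length(x_filtered$samples)
  if (start_sample < 0L || end_sample > n || end_sample <= start_sample) {
    stop("event lies outside the filtered signal", call. = FALSE)
  }
  rect <- abs(x_filtered$samples)
  base <- baseline_values(rect, baseline)
  thr <- mean(base) + p$peak_sd * stats::sd(base)
  seg <- rect[(start_sample + 1L):end_sample]
  pk <- local_maxima(seg)
  sum(seg[pk] > thr) >= p$min_peaks
}

#' Full RMS ripple detector
#'
#' [detect_candidates()] followed by [confirm_hfo()] screening; surviving
#' events carry their peak RMS as score and the label `"unlabeled"`.
#'
#' @inheritParams detect_candidates
#' @return an [event_table()].
#' @export
staba_detect <- function(x, p = detector_params(band = bandpass_spec(fs = x$fs)),
                         baseline = NULL) {
  x <- as_signal1d(x)
  cand <- detect_candidates(x, p, baseline)
  if (nrow(cand) == 0L) return(cand)
  xf <- bandpass(x, p$band)
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    confirm_hfo(xf, cand$start_sample[i], cand$end_sample[i], p, baseline)
  }, logical(1))
  cand[keep, , drop = FALSE]
}
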