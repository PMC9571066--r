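#' Morphological classifier parameters
#'
#' Window sizes for the spike-versus-ripple classifier: the rectified first
#' difference of the raw trace is smoothed with a `smooth_ms` moving
#' average, closed with a `close_ms` window to envelope events, and opened
#' with an `open_ms` window to truncate sharp spikes down towards the
#' background. `open_ms` is the tunable parameter of the method (swept
#' over 1-8 ms, validated default 4 ms); `close_ms` is an uncritical 1 ms.
#'
#' @param smooth_ms moving-average window (ms), default 10.
#' @param close_ms closing window (ms), default 1.
#' @param open_ms opening window (ms), default 4.
#' @param context_ms raw-signal context taken on each side of an event so
#'   the opening has genuine background to truncate to, default 100.
#' @return an object of class `morph_params`.
#' @export
morph_params <- function(smooth_ms = 10, close_ms = 1, open_ms = 4,
                         context_ms = 100) {
  stopifnot(smooth_ms > 0, close_ms > 0, open_ms > 0, context_ms >= 0)
  structure(list(smooth_ms = smooth_ms, close_ms = close_ms,
                 open_ms = open_ms, context_ms = context_ms),
            class = "morph_params")
}

# Event segment with context, plus the core event position inside it
# (1-based index range). Context is clamped to the recording bounds.
event_context <- function(x, start_sample, end_sample, context_ms) {
  n <- length(x$samples)
  if (start_sample < 0L || end_sample > n || end_sample <= start_sample) {
    stop("event lies outside the recording", call. = FALSE)
  }
  ctx <- as.integer(round(context_ms * x$fs / 1000))
  a <- max(0L, start_sample - ctx)
  b <- min(n, end_sample + ctx)
  list(segment = signal1d(x$samples[(a + 1L):b], x$fs),
       core = c(start_sample - a + 1L, end_sample - a))
}

#' Conditioned feature signal for one event
#'
#' Extracts the event plus `context_ms` on each side from the raw
#' recording, then applies the rectified first difference followed by a
#' `smooth_ms` moving average. Spikes show up as a dominant hump at the
#' spike flanks; oscillatory ripples produce a much lower, flatter profile
#' bounded by their amplitude times angular frequency.
#'
#' @param x the raw [signal1d()] recording.
#' @param start_sample,end_sample 0-based half-open event bounds.
#' @param mp a [morph_params()].
#' @return a [signal1d()] covering the event plus context.
#' @export
feature_signal <- function(x, start_sample, end_sample, mp = morph_params()) {
  x <- as_signal1d(x)
  ec <- event_context(x, start_sample, end_sample, mp$context_ms)
  moving_average(rectified_first_difference(ec$segment), mp$smooth_ms)
}

#' Morphological features of one event
#'
#' Computes the feature signal, closes it with `close_ms` (the enveloped
#' event) and opens the envelope with `open_ms` (the truncated event).
#' `envelope_peak` and `truncated_level` are the maxima of the two signals
#' over the core event samples (context excluded). Anti-extensivity of
#' opening guarantees `truncated_level <= envelope_peak`.
#'
#' @inheritParams feature_signal
#' @return an object of class `event_features` with fields
#'   `envelope_peak`, `truncated_level` and `open_ms`.
#' @export
extract_features <- function(x, start_sample, end_sample, mp = morph_params()) {
  x <- as_signal1d(x)
  ec <- event_context(x, start_sample, end_sample, mp$context_ms)
  feat <- moving_average(rectified_first_difference(ec$segment), mp$smooth_ms)
  envelope <- morph_close(feat, struct_window(mp$close_ms, x$fs))
  truncated <- morph_open(envelope, struct_window(mp$open_ms, x$fs))
  core <- ec$core[1]:ec$core[2]
  structure(list(envelope_peak = max(envelope$samples[core]),
                 truncated_level = max(truncated$samples[core]),
                 open_ms = mp$open_ms),
            class = "event_features")
}

# Features for every row of an event table; returns a data.frame.
features_for_events <- function(x, events, mp) {
  if (nrow(events) == 0L) {
    return(data.frame(envelope_peak = numeric(), truncated_level = numeric()))
  }
  fl <- lapply(seq_len(nrow(events)), function(i) {
    f <- extract_features(x, events$start_sample[i], events$end_sample[i], mp)
    c(f$envelope_peak, f$truncated_level)
  })
  m <- do.call(rbind, fl)
  data.frame(envelope_peak = m[, 1], truncated_level = m[, 2])
}

#' Fit the dynamic spike threshold
#'
#' The threshold is the maximum truncated level over all training events:
#' after opening, sharp spikes collapse towards the background, so the
#' largest surviving (truncated) level marks the boundary above which an
#' event's envelope peak betrays a spike.
#'
#' @param x the raw [signal1d()] recording.
#' @param events an [event_table()] of training events (>= 1 row).
#' @param mp a [morph_params()].
#' @return an object of class `dynamic_threshold` with fields `value`,
#'   `n_training_events` and `open_ms`.
#' @export
fit_threshold <- function(x, events, mp = morph_params()) {
  if (nrow(events) < 1L) stop("training set must contain at least one event", call. = FALSE)
  fe <- features_for_events(x, events, mp)
  structure(list(value = max(fe$truncated_level),
                 n_training_events = nrow(events),
                 open_ms = mp$open_ms),
            class = "dynamic_threshold")
}

#' @export
print.dynamic_threshold <- function(x, ...) {
  cat(sprintf("<dynamic_threshold: %.6g (open %g ms, %d training events)>\n",
              x$value, x$open_ms, x$n_training_events))
  invisible(x)
}

#' Classify one event as spike or ripple
#'
#' An event is called a spike when its closing-envelope peak strictly
#' exceeds the dynamic threshold; otherwise it is a ripple.
#'
#' @param f an `event_features` object from [extract_features()].
#' @param th a `dynamic_threshold` from [fit_threshold()].
#' @return `"spike"` or `"ripple"`.
#' @export
classify_event <- function(f, th) {
  stopifnot(inherits(f, "event_features"), inherits(th, "dynamic_threshold"))
  if (abs(f$open_ms - th$open_ms) > 1e-12) {
    stop("features and threshold were computed with different opening windows",
         call. = FALSE)
  }
  if (f$envelope_peak > th$value) "spike" else "ripple"
}

#' Classify every event in a table
#'
#' @param x the raw [signal1d()] recording.
#' @param events an [event_table()].
#' @param th a `dynamic_threshold` from [fit_threshold()].
#' @param mp a [morph_params()]; its `open_ms` must match `th$open_ms`.
#' @return `events` with `label` set to `"spike"`/`"ripple"` and `score`
#'   set to the envelope peak.
#' @export
classify_events <- function(x, events, th, mp = morph_params(open_ms = th$open_ms)) {
  if (abs(mp$open_ms - th$open_ms) > 1e-12) {
    stop("morph_params open_ms does not match the threshold's open_ms", call. = FALSE)
  }
  if (nrow(events) == 0L) return(events)
  fe <- features_for_events(x, events, mp)
  events$label <- ifelse(fe$envelope_peak > th$value, "spike", "ripple")
  events$score <- fe$envelope_peak
  events
}

#' Default opening-window sweep (ms)
#' @export
default_sweep_windows <- function() c(1, 2, 3, 3.4, 4, 4.6, 5, 5.4, 6, 7, 8)

#' Sweep the opening window and measure SE/FDR
#'
#' For each opening window the threshold is refit on the labelled training
#' events, all training events are classified, and sensitivity (SE), false
#' detection rate (FDR) and the ROC distance to the ideal point (0 FDR,
#' 100% SE) are computed with spikes as the positive class.
#'
#' @param x the raw [signal1d()] recording.
#' @param events an [event_table()] whose labels are all `"spike"` or
#'   `"ripple"` (ground truth).
#' @param windows_ms opening windows to sweep, in ms.
#' @param mp a [morph_params()] providing the fixed smoothing/closing
#'   windows.
#' @return a `data.frame` of class `roc_points` with columns `window_ms`,
#'   `TP`, `FP`, `TN`, `FN`, `sensitivity`, `fdr`, `distance`, `threshold`.
#' @export
sweep_open_windows <- function(x, events, windows_ms = default_sweep_windows(),
                               mp = morph_params()) {
  if (nrow(events) == 0L) stop("no events to sweep", call. = FALSE)
  if (!all(events$label %in% c("spike", "ripple"))) {
    stop("sweep requires ground-truth labels in {spike, ripple}", call. = FALSE)
  }
  if (!any(events$label == "spike")) {
    stop("no spikes in the training set: sensitivity is undefined", call. = FALSE)
  }
  rows <- lapply(windows_ms, function(w) {
    mpw <- morph_params(mp$smooth_ms, mp$close_ms, w, mp$context_ms)
    fe <- features_for_events(x, events, mpw)
    thr <- max(fe$truncated_level)
    pred <- ifelse(fe$envelope_peak > thr, "spike", "ripple")
    cc <- confusion(pred, events$label)
    se <- sensitivity(cc)
    fd <- false_detection_rate(cc)
    data.frame(window_ms = w, TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN,
               sensitivity = se, fdr = fd, distance = roc_distance(se, fd),
               threshold = thr)
  })
  structure(do.call(rbind, rows), class = c("roc_points", "data.frame"))
}
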