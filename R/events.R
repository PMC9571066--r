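EVENT_LABELS <- c("ripple", "spike", "sharp_transient", "unlabeled")

#' Event table
#'
#' Events are half-open, 0-based sample intervals `[start_sample,
#' end_sample)` with an optional class label and score. This is the single
#' event representation used by the detector, the classifier, the
#' evaluation layer and the CSV serialisation.
#'
#' @param start_sample integer vector, 0-based inclusive starts.
#' @param end_sample integer vector, exclusive ends (`end > start`).
#' @param label character vector in `c("ripple", "spike",
#'   "sharp_transient", "unlabeled")`; recycled.
#' @param score optional numeric score (e.g. peak RMS); recycled.
#' @return a `data.frame` with class `event_table`.
#' @export
event_table <- function(start_sample = integer(), end_sample = integer(),
                        label = "unlabeled", score = NA_real_) {
  n <- length(start_sample)
  if (length(end_sample) != n) stop("start/end length mismatch", call. = FALSE)
  start_sample <- as.integer(round(start_sample))
  end_sample <- as.integer(round(end_sample))
  label <- rep_len(as.character(label), n)
  score <- rep_len(as.numeric(score), n)
  if (n > 0) {
    if (any(start_sample < 0L)) stop("start_sample must be >= 0", call. = FALSE)
    if (any(end_sample <= start_sample)) stop("end_sample must exceed start_sample", call. = FALSE)
    bad <- !label %in% EVENT_LABELS
    if (any(bad)) stop(sprintf("unknown label(s): %s", paste(unique(label[bad]), collapse = ", ")),
                       call. = FALSE)
  }
  structure(data.frame(start_sample = start_sample, end_sample = end_sample,
                       label = label, score = score,
                       stringsAsFactors = FALSE),
            class = c("event_table", "data.frame"))
}

as_event_table <- function(df) {
  event_table(df$start_sample, df$end_sample,
              if (is.null(df$label)) "unlabeled" else df$label,
              if (is.null(df$score)) NA_real_ else df$score)
}

#' Event durations in milliseconds
#' @param events an [event_table()].
#' @param fs sampling rate in Hz.
#' @return numeric vector of durations.
#' @export
event_duration_ms <- function(events, fs) {
  (events$end_sample - events$start_sample) / fs * 1000
}

# Pairwise overlap (in samples) between one interval and a table of
# intervals; half-open arithmetic.
overlap_samples <- function(s, e, starts, ends) {
  pmax(0L, pmin(e, ends) - pmax(s, starts))
}

#' Label events by overlap with a ground-truth table
#'
#' Each event receives the label of the ground-truth event it overlaps
#' most, provided the overlap covers at least `min_overlap` of the shorter
#' of the two intervals; otherwise it stays `"unlabeled"`.
#'
#' @param events an [event_table()] (e.g. detector output).
#' @param truth a labelled [event_table()].
#' @param min_overlap minimum overlap fraction of the shorter interval.
#' @return `events` with the `label` column filled in.
#' @export
match_to_truth <- function(events, truth, min_overlap = 0.5) {
  if (nrow(events) == 0L || nrow(truth) == 0L) return(events)
  lab <- events$label
  for (i in seq_len(nrow(events))) {
    ov <- overlap_samples(events$start_sample[i], events$end_sample[i],
                          truth$start_sample, truth$end_sample)
    if (all(ov == 0L)) next
    j <- which.max(ov)
    shorter <- min(events$end_sample[i] - events$start_sample[i],
                   truth$end_sample[j] - truth$start_sample[j])
    if (ov[j] >= min_overlap * shorter) lab[i] <- truth$label[j]
  }
  events$label <- lab
  events
}

#' Fraction of ground-truth events recovered by a detection table
#'
#' A truth event counts as recovered when some detection overlaps it by at
#' least `min_overlap` of the shorter of the two intervals.
#'
#' @inheritParams match_to_truth
#' @param label restrict to truth events with this label (`NULL` = all).
#' @return scalar recovery fraction in `[0, 1]`.
#' @export
recovery_fraction <- function(events, truth, label = NULL, min_overlap = 0.5) {
  if (!is.null(label)) truth <- truth[truth$label == label, , drop = FALSE]
  if (nrow(truth) == 0L) stop("no ground-truth events to recover", call. = FALSE)
  if (nrow(events) == 0L) return(0)
  hit <- vapply(seq_len(nrow(truth)), function(j) {
    ov <- overlap_samples(truth$start_sample[j], truth$end_sample[j],
                          events$start_sample, events$end_sample)
    shorter <- pmin(truth$end_sample[j] - truth$start_sample[j],
                    events$end_sample - events$start_sample)
    any(ov >= min_overlap * shorter & ov > 0L)
  }, logical(1))
  mean(hit)
}
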