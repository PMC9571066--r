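#' Event-level confusion counts
#'
#' Spike is the positive class throughout: TP = spikes detected as spikes,
#' FP = ripples detected as spikes, TN = ripples detected as ripples,
#' FN = spikes detected as ripples.
#'
#' @param predicted character vector of predicted labels in
#'   `c("spike", "ripple")`.
#' @param truth character vector of true labels, same length.
#' @return an object of class `confusion_counts` with fields `TP`, `FP`,
#'   `TN`, `FN`.
#' @export
confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have the same length", call. = FALSE)
  }
  ok <- c("spike", "ripple")
  if (!all(predicted %in% ok) || !all(truth %in% ok)) {
    stop("labels must be 'spike' or 'ripple'", call. = FALSE)
  }
  structure(list(TP = sum(predicted == "spike" & truth == "spike"),
                 FP = sum(predicted == "spike" & truth == "ripple"),
                 TN = sum(predicted == "ripple" & truth == "ripple"),
                 FN = sum(predicted == "ripple" & truth == "spike")),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion: TP=%d FP=%d TN=%d FN=%d>\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Sensitivity, SE = TP / (TP + FN)
#'
#' @param cc a [confusion()] object, or a list with fields `TP` and `FN`.
#' @return sensitivity in `[0, 1]`; error (never a silent 0) when
#'   `TP + FN == 0`.
#' @export
sensitivity <- function(cc) {
  if (cc$TP + cc$FN == 0) stop("sensitivity undefined: no true spikes (TP + FN = 0)", call. = FALSE)
  cc$TP / (cc$TP + cc$FN)
}

#' False detection rate, FDR = FP / (FP + TP)
#'
#' @param cc a [confusion()] object, or a list with fields `FP` and `TP`.
#' @return FDR in `[0, 1]`; error when `FP + TP == 0`.
#' @export
false_detection_rate <- function(cc) {
  if (cc$FP + cc$TP == 0) stop("FDR undefined: nothing detected as spike (FP + TP = 0)", call. = FALSE)
  cc$FP / (cc$FP + cc$TP)
}

#' Euclidean ROC distance to the ideal operating point
#'
#' Distance from an (FDR, SE) pair to the ideal point (0% FDR, 100% SE):
#' `sqrt(fdr^2 + (1 - se)^2)`.
#'
#' @param se sensitivity in `[0, 1]`.
#' @param fdr false detection rate in `[0, 1]`.
#' @return distance in `[0, sqrt(2)]`.
#' @export
roc_distance <- function(se, fdr) {
  if (any(se < 0 | se > 1) || any(fdr < 0 | fdr > 1)) {
    stop("se and fdr must lie in [0, 1]", call. = FALSE)
  }
  sqrt(fdr^2 + (1 - se)^2)
}

#' Select the optimal operating point of a window sweep
#'
#' Returns the sweep row with the smallest ROC distance to (0% FDR, 100%
#' SE); ties are broken in favour of the smaller window.
#'
#' @param points a `roc_points` data.frame from [sweep_open_windows()], or
#'   any data.frame with columns `window_ms`, `sensitivity`, `fdr` (the
#'   `distance` column is recomputed if absent).
#' @return the selected row (one-row data.frame).
#' @export
select_optimal_window <- function(points) {
  if (nrow(points) == 0L) stop("no ROC points to select from", call. = FALSE)
  if (is.null(points$distance)) {
    points$distance <- roc_distance(points$sensitivity, points$fdr)
  }
  ord <- order(points$distance, points$window_ms)
  points[ord[1L], , drop = FALSE]
}

#' Round percentages half away from zero
#'
#' Display convention for SE/FDR percentages; raw fractions are always
#' retained by the functions that compute them.
#'
#' @param p fraction(s) in `[0, 1]`.
#' @return integer percentage(s).
#' @export
percent_round <- function(p) {
  x <- 100 * p
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Repeated stratified cross-validation of the spike classifier
#'
#' For each repeat a stratified random split of the labelled events is
#' drawn; the opening-window sweep runs on the training half, the optimal
#' window is selected by ROC distance, the threshold is refit on the
#' training half at that window, and SE/FDR are measured on the held-out
#' half. Everything is a pure function of the seed.
#'
#' @param x the raw [signal1d()] recording.
#' @param events an [event_table()] with ground-truth labels `"spike"` /
#'   `"ripple"`, both classes present.
#' @param n_repeats number of repeats (default 10).
#' @param train_fraction fraction of each class assigned to training
#'   (default 0.5).
#' @param windows_ms opening windows for the sweep.
#' @param mp fixed [morph_params()].
#' @param seed integer seed.
#' @param max_retries resampling attempts when a split leaves a class
#'   empty on either side.
#' @return a list with `per_repeat` (data.frame: repeat index, selected
#'   window, threshold, test SE/FDR), `summary` (mean/SD of SE and FDR),
#'   and `modal_window_ms`.
#' @export
cross_validate <- function(x, events, n_repeats = 10, train_fraction = 0.5,
                           windows_ms = default_sweep_windows(),
                           mp = morph_params(), seed = 1L, max_retries = 20L) {
  stopifnot(n_repeats >= 1, train_fraction > 0, train_fraction < 1)
  labs <- events$label
  if (!all(labs %in% c("spike", "ripple")) || !all(c("spike", "ripple") %in% labs)) {
    stop("cross-validation requires both spike and ripple events", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  split_once <- function() {
    train_idx <- unlist(lapply(c("spike", "ripple"), function(l) {
      idx <- which(labs == l)
      n_train <- min(max(1L, round(train_fraction * length(idx))), length(idx) - 1L)
      sample(idx, n_train)
    }))
    sort(train_idx)
  }
  rows <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    tries <- 0L
    repeat {
      tr <- split_once()
      te <- setdiff(seq_along(labs), tr)
      ok <- all(c("spike", "ripple") %in% labs[tr]) && any(labs[te] == "spike")
      if (ok) break
      tries <- tries + 1L
      if (tries > max_retries) stop("could not draw a split with spikes on both sides", call. = FALSE)
    }
    sw <- sweep_open_windows(x, events[tr, , drop = FALSE], windows_ms, mp)
    best <- select_optimal_window(sw)
    mpw <- morph_params(mp$smooth_ms, mp$close_ms, best$window_ms, mp$context_ms)
    th <- fit_threshold(x, events[tr, , drop = FALSE], mpw)
    pred <- classify_events(x, events[te, , drop = FALSE], th, mpw)
    cc <- confusion(pred$label, labs[te])
    rows[[r]] <- data.frame(repeat_index = r, window_ms = best$window_ms,
                            threshold = th$value,
                            sensitivity = sensitivity(cc),
                            fdr = if (cc$FP + cc$TP > 0) false_detection_rate(cc) else NA_real_,
                            TP = cc$TP, FP = cc$FP, TN = cc$TN, FN = cc$FN)
  }
  per_repeat <- do.call(rbind, rows)
  win_tab <- table(per_repeat$window_ms)
  modal <- as.numeric(names(win_tab)[which.max(win_tab)])
  list(per_repeat = per_repeat,
       summary = data.frame(
         mean_sensitivity = mean(per_repeat$sensitivity),
         sd_sensitivity = stats::sd(per_repeat$sensitivity),
         mean_fdr = mean(per_repeat$fdr, na.rm = TRUE),
         sd_fdr = stats::sd(per_repeat$fdr, na.rm = TRUE)),
       modal_window_ms = modal)
}
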