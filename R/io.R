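pkg_version <- function() as.character(utils::packageVersion("morphripple"))

provenance_lines <- function(extra = character()) {
  c(sprintf("# morphripple %s", pkg_version()), paste0("# ", extra))
}

#' Write a signal to CSV
#'
#' Plain-text format: comment lines starting with `#` (including a
#' `# fs=<Hz>` line), a header, and `sample_index,value` rows with 0-based
#' indices.
#'
#' @param x a [signal1d()].
#' @param path output path.
#' @param extra_comments additional provenance comment lines (without the
#'   leading `#`).
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(x, path, extra_comments = character()) {
  x <- as_signal1d(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(provenance_lines(extra_comments), sprintf("# fs=%.10g", x$fs),
               "sample_index,value"), con)
  utils::write.table(
    data.frame(sample_index = seq_along(x$samples) - 1L, value = x$samples),
    con, sep = ",", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a signal from CSV
#'
#' @param path a CSV written by [write_signal_csv()] or any
#'   comma/tab-separated file whose last column holds the samples.
#' @param fs sampling rate override; required when the file carries no
#'   `# fs=<Hz>` comment line.
#' @return a [signal1d()].
#' @export
read_signal_csv <- function(path, fs = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  fs_line <- grep("^#\\s*fs\\s*=", head_lines, value = TRUE)
  if (is.null(fs)) {
    if (length(fs_line) == 0L) {
      stop("no '# fs=<Hz>' header line; pass `fs` explicitly", call. = FALSE)
    }
    fs <- as.numeric(sub("^#\\s*fs\\s*=\\s*", "", fs_line[1L]))
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (nrow(df) == 0L) stop("empty signal: no sample rows in file", call. = FALSE)
  signal1d(df[[ncol(df)]], fs)
}

#' Write an event table to CSV
#'
#' Columns: `start_sample`, `end_sample`, `start_s`, `end_s`, `label`,
#' `score`. Samples are 0-based half-open and authoritative; the seconds
#' columns are derived conveniences.
#'
#' @param events an [event_table()].
#' @param path output path.
#' @param fs sampling rate used to derive the seconds columns.
#' @param extra_comments provenance comment lines.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path, fs, extra_comments = character()) {
  df <- data.frame(start_sample = events$start_sample,
                   end_sample = events$end_sample,
                   start_s = events$start_sample / fs,
                   end_s = events$end_sample / fs,
                   label = events$label, score = events$score)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(provenance_lines(extra_comments), sprintf("# fs=%.10g", fs)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an event table from CSV
#'
#' Validates the header and every row; overlapping events are preserved
#' verbatim (no silent merging).
#'
#' @param path a CSV written by [write_events()].
#' @return an [event_table()].
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("start_sample", "end_sample", "label")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("event file lacks column(s): %s", paste(missing_cols, collapse = ", ")),
         call. = FALSE)
  }
  if (nrow(df) == 0L) return(event_table())
  bad <- which(df$end_sample <= df$start_sample)
  if (length(bad) > 0L) {
    stop(sprintf("row %d: start_sample >= end_sample", bad[1L]), call. = FALSE)
  }
  bad <- which(!df$label %in% EVENT_LABELS)
  if (length(bad) > 0L) {
    stop(sprintf("row %d: unknown label '%s'", bad[1L], df$label[bad[1L]]), call. = FALSE)
  }
  as_event_table(df)
}

#' Read a signal from CSV or EDF
#'
#' Dispatches on the file extension: `.edf` goes to [read_edf()], anything
#' else is treated as delimited text via [read_signal_csv()].
#'
#' @param path input path.
#' @param fs sampling-rate override (CSV only).
#' @param channel channel name or 1-based index (EDF only).
#' @return a [signal1d()].
#' @export
read_signal <- function(path, fs = NULL, channel = 1L) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") {
    read_edf(path, channel)
  } else if (ext %in% c("csv", "tsv", "txt")) {
    read_signal_csv(path, fs)
  } else {
    stop(sprintf("unknown signal format '.%s' (expected .edf or .csv)", ext),
         call. = FALSE)
  }
}
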