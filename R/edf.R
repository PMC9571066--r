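# Minimal European Data Format (EDF) reader/writer. EDF is a fixed-layout
# ASCII header (256 bytes + 256 per signal) followed by data records of
# 16-bit little-endian integers; physical values are recovered by linear
# scaling between the stated digital and physical ranges. Only what the
# package needs is implemented: continuous single- or multi-channel
# records with one record per second. No R EDF reader is available in the
# target environment, which is why this lives here.

edf_pad <- function(s, width) {
  s <- as.character(s)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write signals to an EDF file
#'
#' One data record per second; the final partial second is zero-padded, so
#' a read-back signal may be up to one second longer than the input unless
#' the duration is a whole number of seconds. Samples are quantised to 16
#' bits over the per-channel physical range.
#'
#' @param signals a [signal1d()] or a named list of them (equal `fs` and
#'   length).
#' @param path output path.
#' @param labels channel labels (defaults to list names or `ch1`, ...).
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, path, labels = NULL) {
  if (inherits(signals, "signal1d")) signals <- list(signals)
  ns <- length(signals)
  fs <- signals[[1L]]$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  n <- length(signals[[1L]]$samples)
  for (s in signals) {
    if (length(s$samples) != n || s$fs != fs) stop("all channels must share fs and length", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- names(signals)
    if (is.null(labels) || any(labels == "")) labels <- paste0("ch", seq_len(ns))
  }
  n_rec <- as.integer(ceiling(n / fs))
  phys_min <- phys_max <- numeric(ns)
  digital <- vector("list", ns)
  for (i in seq_len(ns)) {
    v <- c(signals[[i]]$samples, numeric(n_rec * fs - n))
    lo <- min(v); hi <- max(v)
    if (hi - lo < 1e-12) { hi <- lo + 1 }
    phys_min[i] <- lo; phys_max[i] <- hi
    digital[[i]] <- as.integer(round((v - lo) / (hi - lo) * 65535 - 32768))
  }
  header_bytes <- 256L * (ns + 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, width) writeChar(edf_pad(s, width), con, nchars = width, eos = NULL)
  wr("0", 8); wr("X X X X", 80); wr("Startdate X X X X", 80)
  wr("01.01.00", 8); wr("00.00.00", 8)
  wr(header_bytes, 8); wr("", 44); wr(n_rec, 8); wr("1", 8); wr(ns, 4)
  for (i in seq_len(ns)) wr(labels[i], 16)
  for (i in seq_len(ns)) wr("synthetic", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(sprintf("%.8g", phys_min[i]), 8)
  for (i in seq_len(ns)) wr(sprintf("%.8g", phys_max[i]), 8)
  for (i in seq_len(ns)) wr("-32768", 8)
  for (i in seq_len(ns)) wr("32767", 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      writeBin(digital[[i]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read one channel from an EDF file
#'
#' @param path an EDF file.
#' @param channel channel label or 1-based index.
#' @return a [signal1d()].
#' @export
read_edf <- function(path, channel = 1L) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  rdn <- function(width) as.numeric(rd(width))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rdn(8); rd(44)
  n_rec <- as.integer(rdn(8))
  rec_dur <- rdn(8)
  ns <- as.integer(rdn(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  phys_min <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  phys_max <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  dig_min <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  dig_max <- vapply(seq_len(ns), function(i) rdn(8), numeric(1))
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rdn(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (is.character(channel)) {
    ci <- match(channel, labels)
    if (is.na(ci)) stop(sprintf("channel '%s' not found (have: %s)", channel,
                                paste(labels, collapse = ", ")), call. = FALSE)
  } else {
    ci <- as.integer(channel)
    if (ci < 1L || ci > ns) stop(sprintf("channel index %d out of range 1..%d", ci, ns),
                                 call. = FALSE)
  }
  out <- numeric(n_rec * spr[ci])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      vals <- readBin(con, integer(), n = spr[i], size = 2L, endian = "little")
      if (i == ci) out[((r - 1L) * spr[ci] + 1L):(r * spr[ci])] <- vals
    }
  }
  scale <- (phys_max[ci] - phys_min[ci]) / (dig_max[ci] - dig_min[ci])
  signal1d(phys_min[ci] + (out - dig_min[ci]) * scale, spr[ci] / rec_dur)
}
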