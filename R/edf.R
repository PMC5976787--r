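# Minimal European Data Format (EDF) I/O.
#
# No EDF package is available in this stack, so the subset of the format the
# pipeline needs is implemented directly: one continuous recording, 16-bit
# samples, identical sampling rate on every signal, 1-second data records.
# The last record is zero-padded; the true sample count is carried in the
# reserved header field so a round trip is exact in length.

edf_pad <- function(s, width) {
  s <- substr(s, 1L, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Physical units are microvolts; each channel is scaled independently to
#' the full 16-bit digital range, so the quantization step is
#' `2 * max(abs(channel)) / 65534`.
#'
#' @param recording an `eeg_recording` (see [simulate_recording()]). The
#'   sampling rate must be a whole number of Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_edf()], [write_events_csv()]
#' @export
write_edf <- function(recording, path) {
  stopifnot(inherits(recording, "eeg_recording"))
  srate <- recording$srate
  if (srate != round(srate)) stop_invalid("EDF writer requires integer srate")
  srate <- as.integer(srate)
  data <- recording$data
  n_ch <- nrow(data)
  n_samp <- ncol(data)
  n_rec <- as.integer(ceiling(n_samp / srate))
  labels <- recording$sensors$labels

  pm <- apply(abs(data), 1, max)
  pm <- ifelse(pm > 0, pm, 1)          # avoid zero physical range
  dig_max <- 32767L
  dig_min <- -32767L

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)

  # fixed 256-byte header
  wr("0", 8)
  wr(recording$meta$subject_id %||% "X", 80)
  wr("Startdate 01-JAN-2000", 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(as.character(256L + 256L * n_ch), 8)
  wr(sprintf("nsamples=%d", n_samp), 44)   # reserved: true sample count
  wr(as.character(n_rec), 8)
  wr("1", 8)                               # record duration, seconds
  wr(as.character(n_ch), 4)

  # per-signal header blocks
  for (s in labels) wr(s, 16)
  for (s in labels) wr("AgAgCl electrode", 80)
  for (s in labels) wr("uV", 8)
  for (i in seq_len(n_ch)) wr(formatC(-pm[i], format = "g", digits = 6), 8)
  for (i in seq_len(n_ch)) wr(formatC(pm[i], format = "g", digits = 6), 8)
  for (i in seq_len(n_ch)) wr(as.character(dig_min), 8)
  for (i in seq_len(n_ch)) wr(as.character(dig_max), 8)
  for (s in labels) wr("", 80)
  for (s in labels) wr(as.character(srate), 8)
  for (s in labels) wr("", 32)

  # data records: per record, per signal, srate int16 samples
  scale <- dig_max / pm
  padded <- matrix(0, n_ch, n_rec * srate)
  padded[, seq_len(n_samp)] <- data
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * srate + 1L):(r * srate)
    dig <- round(padded[, idx, drop = FALSE] * scale)
    dig <- pmin(pmax(dig, dig_min), dig_max)
    writeBin(as.integer(t(dig)), con, size = 2L, endian = "little")
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' Supports continuous 16-bit EDF with a uniform sampling rate across
#' signals. Returns channel data in physical units (microvolts).
#'
#' @param path EDF file path.
#' @return A list with `data` (channels x samples matrix, rownames =
#'   channel labels), `srate` and `labels`.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8); rd(8)
  reserved <- rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))

  labels <- vapply(seq_len(n_ch), function(i) rd(16), "")
  for (i in seq_len(n_ch)) rd(80)
  for (i in seq_len(n_ch)) rd(8)
  phys_min <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 0)
  phys_max <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 0)
  dig_min <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 0)
  dig_max <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(n_ch)) rd(80)
  spr <- vapply(seq_len(n_ch), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(n_ch)) rd(32)
  if (length(unique(spr)) != 1L) {
    stop_invalid("reader supports a single sampling rate across signals")
  }
  srate <- spr[1] / dur

  data <- matrix(0, n_ch, n_rec * spr[1])
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, "integer", n = n_ch * spr[1], size = 2L,
                   signed = TRUE, endian = "little")
    block <- matrix(raw, nrow = spr[1], ncol = n_ch)   # signal-major
    idx <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
    data[, idx] <- t(block) * gain + (phys_min - dig_min * gain)
  }
  m <- regmatches(reserved, regexec("nsamples=([0-9]+)", reserved))[[1]]
  if (length(m) == 2L) data <- data[, seq_len(as.integer(m[2])), drop = FALSE]
  rownames(data) <- labels
  list(data = data, srate = srate, labels = labels)
}

#' Write and read the event table
#'
#' Events are persisted as CSV with columns `sample` (0-based), `onset_s`,
#' `series`, `condition` (STD/TGT) and `test_series` (0/1).
#'
#' @param events data.frame of events (as carried by an `eeg_recording`).
#' @param path CSV path.
#' @return the events data.frame, or the path invisibly for the writer.
#' @name events_io
NULL

#' @rdname events_io
#' @export
write_events_csv <- function(events, path) {
  df <- data.frame(sample = events$sample,
                   onset_s = events$onset_s,
                   series = events$series,
                   condition = events$condition,
                   test_series = as.integer(events$test_series))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname events_io
#' @export
read_events_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("sample", "onset_s", "series", "condition", "test_series")
  if (!all(need %in% names(df))) {
    stop_invalid("events CSV needs columns %s", paste(need, collapse = ", "))
  }
  df$condition <- as.character(df$condition)
  df$test_series <- as.logical(df$test_series)
  df
}
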