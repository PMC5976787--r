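# Continuous recording -> clean condition-averaged evoked responses.
# Conventions: 0-based sample indices in event tables, half-open sample
# intervals, time 0 = stimulus onset.

#' Zero-phase band-pass filter
#'
#' FFT-domain band-pass with raised-cosine transitions (half an octave below
#' the low edge, 10% above the high edge). Being a frequency-domain mask it
#' is exactly zero-phase; no Butterworth design is available in this stack.
#'
#' @param recording an `eeg_recording`.
#' @param l_freq,h_freq pass-band edges in Hz (defaults 0.5 and 40).
#' @return the recording, filtered.
#' @export
bandpass_filter <- function(recording, l_freq = 0.5, h_freq = 40) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (l_freq <= 0 || h_freq <= l_freq) {
    stop_invalid("need 0 < l_freq < h_freq")
  }
  n <- ncol(recording$data)
  f <- seq(0, n - 1) / n * recording$srate
  f <- pmin(f, recording$srate - f)                  # two-sided frequencies
  lo0 <- l_freq / 2
  hi1 <- h_freq * 1.1
  mask <- rep(1, n)
  below <- f < l_freq
  mask[below] <- 0.5 * (1 - cos(pi * pmax(f[below] - lo0, 0) / (l_freq - lo0)))
  above <- f > h_freq
  mask[above] <- 0.5 * (1 + cos(pi * pmin(f[above] - h_freq, hi1 - h_freq) /
                                  (hi1 - h_freq)))
  for (i in seq_len(nrow(recording$data))) {
    recording$data[i, ] <- Re(stats::fft(stats::fft(recording$data[i, ]) * mask,
                                         inverse = TRUE)) / n
  }
  recording
}

#' Cut a continuous recording into stimulus-locked epochs
#'
#' One epoch per event whose full window lies inside the recording. Events
#' of the test (practice) series are dropped by default. The per-epoch,
#' per-channel mean over the baseline interval is subtracted.
#'
#' Sample arithmetic: an event at 0-based sample `s` with window
#' `(w1, w2)` covers samples `[s + round(w1 * srate), s + round(w2 * srate))`
#' — half-open, so the default (-0.2, 0.8) s window at 500 Hz yields exactly
#' 500 samples.
#'
#' @param recording an `eeg_recording`.
#' @param window epoch limits in seconds relative to stimulus onset;
#'   `window[1] < 0 < window[2]`. Default `c(-0.2, 0.8)`.
#' @param baseline baseline interval in seconds, a subset of `window`.
#'   Default `c(-0.2, 0)`.
#' @param exclude_test_series drop events of series 1 (default TRUE).
#' @return Object of class `epoch_set`: `data` (epochs x channels x
#'   samples array, uV), `conditions`, `kept` (logical rejection mask, all
#'   TRUE), `times` (seconds relative to onset), `window`, `baseline`,
#'   `srate`.
#' @export
epoch_recording <- function(recording, window = c(-0.2, 0.8),
                            baseline = c(-0.2, 0),
                            exclude_test_series = TRUE) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (!(window[1] < 0 && 0 < window[2])) {
    stop_invalid("window must straddle stimulus onset: start < 0 < end")
  }
  if (baseline[1] < window[1] || baseline[2] > window[2]) {
    stop_invalid("baseline must lie within the epoch window")
  }
  srate <- recording$srate
  ev <- recording$events
  if (exclude_test_series) ev <- ev[!ev$test_series, , drop = FALSE]

  o1 <- round(window[1] * srate)
  o2 <- round(window[2] * srate)
  n_len <- as.integer(o2 - o1)
  n_samp <- ncol(recording$data)
  start <- ev$sample + o1                     # 0-based start, inclusive
  fits <- start >= 0 & (start + n_len) <= n_samp
  ev <- ev[fits, , drop = FALSE]
  start <- start[fits]

  n_ep <- nrow(ev)
  n_ch <- nrow(recording$data)
  times <- (seq_len(n_len) - 1 + o1) / srate
  b_idx <- which(times >= baseline[1] & times < baseline[2])
  if (n_ep == 0L) {
    warning("no event window fits inside the recording", call. = FALSE)
  }
  data <- array(0, dim = c(n_ep, n_ch, n_len))
  for (i in seq_len(n_ep)) {
    seg <- recording$data[, (start[i] + 1L):(start[i] + n_len), drop = FALSE]
    if (length(b_idx)) seg <- seg - rowMeans(seg[, b_idx, drop = FALSE])
    data[i, , ] <- seg
  }
  structure(
    list(data = data, conditions = ev$condition, kept = rep(TRUE, n_ep),
         times = times, window = window, baseline = baseline, srate = srate,
         meta = recording$meta),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs (%d kept) x %d ch x %d samples, window [%g, %g) s\n",
              length(x$conditions), sum(x$kept), dim(x$data)[2], dim(x$data)[3],
              x$window[1], x$window[2]))
  invisible(x)
}

#' Threshold-based artifact rejection
#'
#' Marks an epoch rejected if any channel's peak-to-peak amplitude exceeds
#' `ptp_threshold` (catching blinks and large transients) or if every
#' channel's peak-to-peak amplitude falls below `flat_threshold` (flat /
#' disconnected segments). Only the `kept` mask changes; data are untouched,
#' and epochs already rejected stay rejected.
#'
#' @param epochs an `epoch_set`.
#' @param ptp_threshold peak-to-peak ceiling, uV (default 150).
#' @param flat_threshold flatness floor, uV (default 0.1).
#' @return the `epoch_set` with an updated `kept` mask.
#' @export
reject_artifacts <- function(epochs, ptp_threshold = 150, flat_threshold = 0.1) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (ptp_threshold <= 0 || flat_threshold <= 0) {
    stop_invalid("thresholds must be positive")
  }
  n_ep <- length(epochs$conditions)
  bad <- logical(n_ep)
  for (i in seq_len(n_ep)) {
    ptp <- apply(epochs$data[i, , , drop = FALSE], 2, function(ch) {
      r <- range(ch)
      r[2] - r[1]
    })
    bad[i] <- any(ptp > ptp_threshold) || all(ptp < flat_threshold)
  }
  epochs$kept <- epochs$kept & !bad
  epochs
}

#' Condition average (evoked response)
#'
#' Sample-wise mean over the kept epochs of one condition.
#'
#' @param epochs an `epoch_set`.
#' @param condition condition label, e.g. "TGT" or "STD".
#' @return Object of class `evoked`: `data` (channels x samples, uV),
#'   `condition`, `n_averaged`, `times`, `window`, `srate`.
#' @export
average_epochs <- function(epochs, condition) {
  stopifnot(inherits(epochs, "epoch_set"))
  sel <- which(epochs$kept & epochs$conditions == condition)
  if (length(sel) == 0L) {
    stop_invalid("no kept epochs for condition '%s'", condition)
  }
  data <- apply(epochs$data[sel, , , drop = FALSE], c(2, 3), mean)
  structure(
    list(data = data, condition = condition, n_averaged = length(sel),
         times = epochs$times, window = epochs$window, srate = epochs$srate),
    class = "evoked"
  )
}

#' @export
print.evoked <- function(x, ...) {
  cat(sprintf("<evoked> %s, mean of %d epochs, %d ch x %d samples\n",
              x$condition, x$n_averaged, nrow(x$data), ncol(x$data)))
  invisible(x)
}
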