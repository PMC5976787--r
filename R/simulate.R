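# Synthetic oddball experiment: stimulus schedules, P300-like source
# activity pushed through the forward model, background noise, blinks.

#' Oddball stimulus schedule
#'
#' Generates the stimulus sequence of a visual oddball experiment: a fixed
#' number of series, each containing `round(target_frac * series_len)`
#' targets (TGT) among standards (STD) in seeded-random order. The first
#' series is a test (practice) series, flagged so downstream stages can
#' exclude it. When feasible, no two targets are consecutive within a
#' series, the usual oddball constraint; if `target_frac > 0.5` makes this
#' infeasible the schedule falls back to an unconstrained shuffle with a
#' warning.
#'
#' With the defaults (4 series of 100 stimuli, 20% targets, 0.5 s display,
#' 1.5 s inter-stimulus interval) the three analysis series contain exactly
#' 60 targets and 240 standards.
#'
#' @param n_series number of series (default 4; the first is a test series).
#' @param series_len stimuli per series (default 100).
#' @param target_frac fraction of targets per series (default 0.2).
#' @param stimulus_duration stimulus display time, seconds (default 0.5).
#' @param isi inter-stimulus interval (offset to next onset), seconds
#'   (default 1.5).
#' @param seed integer seed for the target placement.
#' @return Object of class `stim_schedule`: `events` data.frame with
#'   columns `series`, `onset_s`, `condition`, `test_series`; plus the
#'   generating parameters.
#' @examples
#' sch <- make_schedule(seed = 1)
#' table(sch$events$condition[!sch$events$test_series])  # 240 STD, 60 TGT
#' @export
make_schedule <- function(n_series = 4L, series_len = 100L, target_frac = 0.2,
                          stimulus_duration = 0.5, isi = 1.5, seed = 1L) {
  n_series <- as.integer(n_series)
  series_len <- as.integer(series_len)
  if (n_series < 1L || series_len < 1L) {
    stop_invalid("n_series and series_len must be positive")
  }
  if (target_frac < 0 || target_frac > 1) {
    stop_invalid("target_frac must be in [0, 1]")
  }
  n_tgt <- as.integer(round(target_frac * series_len))
  soa <- stimulus_duration + isi

  conditions <- with_seed(seed, {
    lapply(seq_len(n_series), function(s) {
      cond <- rep("STD", series_len)
      if (n_tgt == 0L) return(cond)
      if (n_tgt <= series_len - n_tgt + 1L) {
        # uniform placement with no two targets adjacent: choose gaps
        pos <- sort(sample.int(series_len - n_tgt + 1L, n_tgt)) +
          seq_len(n_tgt) - 1L
      } else {
        warning("no-two-consecutive-targets infeasible; using plain shuffle",
                call. = FALSE)
        pos <- sample.int(series_len, n_tgt)
      }
      cond[pos] <- "TGT"
      cond
    })
  })

  events <- do.call(rbind, lapply(seq_len(n_series), function(s) {
    k <- seq_len(series_len)
    data.frame(
      series = s,
      onset_s = ((s - 1L) * series_len + (k - 1L)) * soa,
      condition = conditions[[s]],
      test_series = s == 1L
    )
  }))
  structure(
    list(events = events, n_series = n_series, series_len = series_len,
         target_frac = target_frac, stimulus_duration = stimulus_duration,
         isi = isi, seed = seed),
    class = "stim_schedule"
  )
}

#' @export
print.stim_schedule <- function(x, ...) {
  tab <- table(x$events$condition)
  cat(sprintf("<stim_schedule> %d series x %d stimuli (%s), SOA %.3g s\n",
              x$n_series, x$series_len,
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              x$stimulus_duration + x$isi))
  invisible(x)
}

#' P300-like source time course
#'
#' A Gaussian deflection `amplitude * exp(-(t - peak)^2 / (2 width^2))`
#' sampled on the epoch grid, used as the dipole-moment time course of the
#' simulated evoked response. The defaults (peak 0.4 s, width 0.06 s) put
#' more than 95% of the waveform's mass inside the 280-600 ms observation
#' window.
#'
#' @param srate sampling rate, Hz.
#' @param peak_latency peak time after stimulus onset, seconds (default 0.4).
#' @param width Gaussian standard deviation, seconds (default 0.06).
#' @param amplitude peak dipole moment, nA*m.
#' @param duration length of the sampled grid, seconds (default 0.8).
#' @return list with `t` (seconds from onset) and `moment` (nA*m).
#' @export
make_p300_waveform <- function(srate, peak_latency = 0.4, width = 0.06,
                               amplitude = 1, duration = 0.8) {
  if (peak_latency <= 0 || width <= 0) {
    stop_invalid("peak_latency and width must be positive")
  }
  t <- seq(0, duration - 1 / srate, by = 1 / srate)
  list(t = t, moment = amplitude * exp(-(t - peak_latency)^2 / (2 * width^2)))
}

#' Noise configuration for the simulator
#'
#' @param white white sensor-noise standard deviation, uV (default 2).
#' @param pink 1/f background standard deviation, uV (default 1).
#' @param alpha amplitude of a common 10 Hz rhythm, uV (default 0).
#' @return named list used by [simulate_recording()].
#' @export
noise_config <- function(white = 2, pink = 1, alpha = 0) {
  list(white = white, pink = pink, alpha = alpha)
}

# 1/f-amplitude noise per channel via spectral shaping, unit variance
pink_noise <- function(n_ch, n_samp) {
  out <- matrix(0, n_ch, n_samp)
  f <- seq(0, floor(n_samp / 2)) / n_samp
  amp <- c(0, 1 / sqrt(f[-1]))                     # no DC
  for (i in seq_len(n_ch)) {
    spec <- complex(modulus = amp,
                    argument = stats::runif(length(amp), 0, 2 * pi))
    full <- c(spec, Conj(rev(spec[2:(n_samp - length(spec) + 1L)])))
    x <- Re(stats::fft(full, inverse = TRUE)) / n_samp
    out[i, ] <- x / stats::sd(x)
  }
  out
}

#' Simulate a continuous oddball EEG recording
#'
#' Places a P300-like current dipole at the centroid voxel of
#' `source_region`, oriented radially, drives it with [make_p300_waveform()]
#' at every stimulus (full amplitude for targets, `std_amplitude` for
#' standards), projects through the lead field, and adds white sensor
#' noise, 1/f background and an optional common 10 Hz rhythm. Two seconds
#' of padding are added before the first and after the last stimulus.
#'
#' @param schedule a `stim_schedule`.
#' @param leadfield a `leadfield`.
#' @param atlas a `ba_atlas` over the lead field's source space.
#' @param source_region region label in `atlas$regions` hosting the dipole.
#' @param tgt_amplitude peak dipole moment for targets, nA*m (default 50,
#'   a typical evoked-response moment giving ~5 uV peak scalp deflection
#'   with the default head model).
#' @param std_amplitude peak moment for standards (default 20% of
#'   `tgt_amplitude`: standard stimuli evoke a weak but nonzero response).
#' @param noise a [noise_config()].
#' @param srate sampling rate, Hz (default 500).
#' @param seed integer seed for all noise draws.
#' @param meta optional `subject_meta` (see [subject_meta()]).
#' @param peak_latency,width P300 waveform parameters passed through.
#' @return Object of class `eeg_recording`: `data` (channels x samples,
#'   uV), `srate`, `events` data.frame (with 0-based `sample` indices),
#'   `sensors`, `meta`, and `truth` (the injected region, voxel and
#'   amplitudes, for parameter-recovery tests).
#' @export
simulate_recording <- function(schedule, leadfield, atlas, source_region,
                               tgt_amplitude = 50,
                               std_amplitude = 0.2 * tgt_amplitude,
                               noise = noise_config(), srate = 500,
                               seed = 1L, meta = subject_meta(),
                               peak_latency = 0.4, width = 0.06) {
  stopifnot(inherits(schedule, "stim_schedule"),
            inherits(leadfield, "leadfield"),
            inherits(atlas, "ba_atlas"))
  if (!source_region %in% atlas$regions) {
    stop_invalid("unknown source region '%s'", source_region)
  }
  pos <- leadfield$sources$positions
  members <- which(atlas$region_of_voxel == source_region)
  centroid <- colMeans(pos[members, , drop = FALSE])
  vox <- members[which.min(colSums((t(pos[members, , drop = FALSE]) - centroid)^2))]
  orient <- pos[vox, ]
  nrm <- sqrt(sum(orient^2))
  orient <- if (nrm > 0) orient / nrm else c(0, 0, 1)   # radial; z at origin
  g <- leadfield$matrix[, (3L * vox - 2L):(3L * vox), drop = FALSE] %*% orient

  pad <- 2
  ev <- schedule$events
  n_samp <- ceiling((max(ev$onset_s) + pad + 1) * srate) + as.integer(pad * srate)
  n_ch <- nrow(leadfield$matrix)

  # source moment time course: one Gaussian bump per stimulus
  wf <- make_p300_waveform(srate, peak_latency, width, amplitude = 1)
  s <- numeric(n_samp)
  ev$sample <- as.integer(round((ev$onset_s + pad) * srate))
  amp <- ifelse(ev$condition == "TGT", tgt_amplitude, std_amplitude)
  for (i in seq_len(nrow(ev))) {
    idx <- ev$sample[i] + seq_along(wf$moment)      # 1-based block
    ok <- idx <= n_samp
    s[idx[ok]] <- s[idx[ok]] + amp[i] * wf$moment[ok]
  }

  data <- g %*% matrix(s, 1L, n_samp)
  data <- data + with_seed(seed, {
    out <- 0
    if (noise$white > 0) {
      out <- out + matrix(stats::rnorm(n_ch * n_samp, sd = noise$white),
                          n_ch, n_samp)
    }
    if (noise$pink > 0) out <- out + noise$pink * pink_noise(n_ch, n_samp)
    if (noise$alpha > 0) {
      t <- seq_len(n_samp) / srate
      phase <- stats::runif(n_ch, 0, 2 * pi)
      out <- out + noise$alpha *
        sin(outer(phase, 2 * pi * 10 * t, `+`))
    }
    if (is.matrix(out)) out else matrix(0, n_ch, n_samp)
  })

  structure(
    list(data = data, srate = srate,
         events = ev[, c("sample", "onset_s", "series", "condition",
                         "test_series")],
         sensors = leadfield$sensors, meta = meta,
         truth = list(region = source_region, voxel = vox,
                      tgt_amplitude = tgt_amplitude,
                      std_amplitude = std_amplitude, seed = seed)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples @ %g Hz, %d events\n",
              nrow(x$data), ncol(x$data), x$srate, nrow(x$events)))
  invisible(x)
}

#' Subject metadata
#'
#' Carries the identifiers and psychophysiological covariates attached to a
#' recording. Diagnosis codes are free ICD-10 strings or "control".
#'
#' @param subject_id nonempty string.
#' @param diagnosis ICD-10 code or "control".
#' @param handedness,sex,age optional demographics.
#' @param covariates free named list of additional parameters.
#' @return object of class `subject_meta`.
#' @export
subject_meta <- function(subject_id = "sim01", diagnosis = "control",
                         handedness = "R", sex = NA_character_,
                         age = NA_real_, covariates = list()) {
  if (!nzchar(subject_id)) stop_invalid("subject_id must be nonempty")
  structure(
    list(subject_id = subject_id, diagnosis = diagnosis,
         handedness = handedness, sex = sex, age = age,
         covariates = covariates),
    class = "subject_meta"
  )
}

#' Inject stereotyped blink artifacts
#'
#' Adds 300 ms half-sine transients with a frontal-dominant spatial pattern
#' (weights decay exponentially with distance from the most anterior
#' sensor) at seeded-random times. Blink onset samples are recorded in
#' `meta$blink_samples` so rejection logic can be tested against ground
#' truth.
#'
#' @param recording an `eeg_recording`.
#' @param rate blink rate, events per minute (default 15).
#' @param amplitude peak amplitude at the most anterior channel, uV
#'   (default 400).
#' @param seed integer seed.
#' @return the recording with artifacts added and blink onsets in
#'   `meta$blink_samples` (0-based).
#' @export
inject_blinks <- function(recording, rate = 15, amplitude = 400, seed = 1L) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (rate < 0) stop_invalid("rate must be nonnegative")
  if (rate == 0) return(recording)
  n_samp <- ncol(recording$data)
  srate <- recording$srate
  dur_min <- n_samp / srate / 60
  blink_len <- round(0.3 * srate)
  template <- sin(pi * seq_len(blink_len) / blink_len)

  pos <- recording$sensors$positions
  anterior <- pos[which.max(pos[, 2]), ]
  d <- sqrt(colSums((t(pos) - anterior)^2))
  w <- exp(-d / 0.05)

  onsets <- with_seed(seed, {
    pop <- max(n_samp - blink_len, 1L)
    n <- min(stats::rpois(1, rate * dur_min), pop)
    sort(sample.int(pop, n, replace = FALSE))
  })
  for (o in onsets) {
    idx <- o + seq_len(blink_len)
    recording$data[, idx] <- recording$data[, idx] +
      amplitude * outer(w, template)
  }
  recording$meta$blink_samples <- c(recording$meta$blink_samples %||% integer(),
                                    onsets - 1L)
  recording
}
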