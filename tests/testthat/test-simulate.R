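test_that("default schedule reproduces the oddball protocol counts", {
  sch <- make_schedule(seed = 11)
  ev <- sch$events
  expect_equal(nrow(ev), 400)
  expect_true(all(ev$test_series == (ev$series == 1)))
  # the three analysis series: 60 targets, 240 standards
  expect_equal(sum(ev$condition == "TGT" & !ev$test_series), 60)
  expect_equal(sum(ev$condition == "STD" & !ev$test_series), 240)
  # 20% targets in every single series
  per_series <- tapply(ev$condition == "TGT", ev$series, sum)
  expect_true(all(per_series == 20))
  expect_true(all(diff(ev$onset_s) > 0))
})

test_that("schedule respects rounding, boundaries, adjacency and the seed", {
  expect_equal(sum(make_schedule(1, 5, 0.2, seed = 2)$events$condition == "TGT"), 1)
  expect_true(all(make_schedule(2, 10, 0, seed = 2)$events$condition == "STD"))

  # conservation and no-two-consecutive targets within a series, many seeds
  for (seed in 1:20) {
    ev <- make_schedule(seed = seed)$events
    expect_equal(sum(ev$condition %in% c("TGT", "STD")), 400)
    for (s in unique(ev$series)) {
      tgt <- ev$condition[ev$series == s] == "TGT"
      expect_false(any(tgt[-1] & tgt[-length(tgt)]))
    }
  }

  expect_identical(make_schedule(seed = 5), make_schedule(seed = 5))
  expect_warning(make_schedule(1, 10, 0.8, seed = 1), "infeasible")
})

test_that("P300 waveform peaks at the stated latency with mass in the window", {
  wf <- make_p300_waveform(500, amplitude = 7)
  expect_equal(wf$moment[which.min(abs(wf$t - 0.4))], 7)
  expect_equal(max(wf$moment), 7)

  expect_true(all(make_p300_waveform(500, amplitude = 0)$moment == 0))

  # >95% of the waveform's mass lies inside [0.28, 0.60] s; the closed-form
  # Gaussian integral (error function) is the oracle
  inside <- wf$t >= 0.28 & wf$t <= 0.60
  expect_gt(sum(wf$moment[inside]) / sum(wf$moment), 0.95)
  frac <- (pnorm(0.60, 0.4, 0.06) - pnorm(0.28, 0.4, 0.06)) /
    (pnorm(0.80, 0.4, 0.06) - pnorm(0, 0.4, 0.06))
  expect_equal(sum(wf$moment[inside]) / sum(wf$moment), frac, tolerance = 1e-3)
})

test_that("forward simulation is linear, deterministic, and target-locked", {
  m <- small_model()
  region <- pick_source_region(m)
  sch <- make_schedule(2, 10, 0.2, seed = 3)
  quiet <- noise_config(white = 0, pink = 0)

  r1 <- simulate_recording(sch, m$lf, m$atlas, region, tgt_amplitude = 20,
                           noise = quiet, srate = 250, seed = 1)
  r2 <- simulate_recording(sch, m$lf, m$atlas, region, tgt_amplitude = 40,
                           noise = quiet, srate = 250, seed = 1)
  expect_equal(r2$data, 2 * r1$data, tolerance = 1e-12)

  # noise-free target epochs peak in the P300 latency range at the sensor
  # nearest the source
  vox <- r1$truth$voxel
  d <- colSums((t(m$sens$positions) - m$src$positions[vox, ])^2)
  best <- which.min(d)
  tgt <- r1$events[r1$events$condition == "TGT", ][1, ]
  idx <- tgt$sample + seq_len(200)            # 0.8 s at 250 Hz, 1-based
  trace <- r1$data[best, idx]
  peak_t <- (which.max(abs(trace)) - 1) / 250
  expect_gt(max(abs(trace)), 0)
  expect_true(peak_t >= 0.35 && peak_t <= 0.45)

  # identical seeds give bit-identical recordings, different seeds differ
  r3 <- simulate_recording(sch, m$lf, m$atlas, region, srate = 250, seed = 9)
  r4 <- simulate_recording(sch, m$lf, m$atlas, region, srate = 250, seed = 9)
  expect_identical(r3$data, r4$data)
  r5 <- simulate_recording(sch, m$lf, m$atlas, region, srate = 250, seed = 10)
  expect_false(identical(r3$data, r5$data))

  expect_error(simulate_recording(sch, m$lf, m$atlas, "BA999", srate = 250),
               "unknown")
})

test_that("zero-amplitude simulation is pure noise with matched conditions", {
  m <- small_model()
  sch <- make_schedule(2, 20, 0.2, seed = 4)
  rec <- simulate_recording(sch, m$lf, m$atlas, pick_source_region(m),
                            tgt_amplitude = 0, std_amplitude = 0,
                            srate = 250, seed = 5)
  ep <- epoch_recording(rec)
  a_t <- average_epochs(ep, "TGT")$data
  a_s <- average_epochs(ep, "STD")$data
  # condition difference is sampling noise only: far smaller than the
  # single-epoch noise floor, and with no systematic offset
  expect_lt(abs(mean(a_t - a_s)), 0.5)
  expect_lt(mean(abs(a_t - a_s)), 2)
})

test_that("1/f background has a falling log-log power spectrum", {
  m <- small_model()
  sch <- make_schedule(1, 8, 0, seed = 1)
  rec <- simulate_recording(sch, m$lf, m$atlas, pick_source_region(m),
                            tgt_amplitude = 0, std_amplitude = 0,
                            noise = noise_config(white = 0, pink = 1),
                            srate = 250, seed = 2)
  x <- rec$data[1, ]
  n <- length(x)
  p <- Mod(fft(x))[2:floor(n / 2)]^2 / n
  f <- (1:(floor(n / 2) - 1)) * 250 / n
  sel <- f >= 1 & f <= 40
  slope <- coef(lm(log(p[sel]) ~ log(f[sel])))[2]
  expect_lt(slope, -0.5)
})

test_that("blink injection is seeded, frontal-dominant and reversible at rate 0", {
  m <- small_model()
  sch <- make_schedule(1, 8, 0.25, seed = 1)
  rec <- simulate_recording(sch, m$lf, m$atlas, pick_source_region(m),
                            tgt_amplitude = 0, std_amplitude = 0,
                            noise = noise_config(white = 0.5, pink = 0),
                            srate = 250, seed = 2)
  expect_identical(inject_blinks(rec, rate = 0), rec)

  b1 <- inject_blinks(rec, rate = 30, amplitude = 400, seed = 7)
  b2 <- inject_blinks(rec, rate = 30, amplitude = 400, seed = 7)
  expect_identical(b1$meta$blink_samples, b2$meta$blink_samples)
  expect_gt(length(b1$meta$blink_samples), 0)

  # peak-to-peak at the most anterior channel exceeds the background
  ant <- which.max(m$sens$positions[, 2])
  ptp <- function(x) diff(range(x))
  expect_gt(ptp(b1$data[ant, ]), 10 * ptp(rec$data[ant, ]))
  # blinks are frontal-dominant: posterior-most channel barely moves
  post <- which.min(m$sens$positions[, 2])
  expect_lt(ptp(b1$data[post, ]) / ptp(b1$data[ant, ]), 0.5)
})

test_that("EDF and events CSV round-trip the recording within 16-bit precision", {
  m <- small_model()
  sch <- make_schedule(1, 8, 0.25, seed = 1)
  rec <- simulate_recording(sch, m$lf, m$atlas, pick_source_region(m),
                            srate = 250, seed = 3)
  f <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, f)
  back <- read_edf(f)
  expect_equal(back$srate, 250)
  expect_equal(back$labels, rec$sensors$labels)
  expect_equal(dim(back$data), dim(rec$data))
  qstep <- max(abs(rec$data)) / 32767
  expect_lt(max(abs(back$data - rec$data)), 2 * qstep)

  ef <- withr::local_tempfile(fileext = ".csv")
  write_events_csv(rec$events, ef)
  ev <- read_events_csv(ef)
  expect_equal(ev$sample, rec$events$sample)
  expect_equal(ev$condition, rec$events$condition)
  expect_equal(ev$test_series, rec$events$test_series)
})
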