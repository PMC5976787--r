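test_that("epoching uses half-open windows with exact sample arithmetic", {
  # event at sample 1000 @ 500 Hz, window (-0.2, 0.8): samples [900, 1400)
  set.seed(1)
  data <- matrix(rnorm(4 * 2000), 4, 2000)
  ev <- data.frame(sample = 1000L, onset_s = 2, series = 2L,
                   condition = "TGT", test_series = FALSE)
  rec <- as_recording(data, 500, ev)
  ep <- epoch_recording(rec)
  expect_equal(dim(ep$data), c(1, 4, 500))
  expect_equal(ep$times[1], -0.2)
  expect_equal(ep$times[500], 0.8 - 1 / 500)
  # data map: epoch equals raw segment minus its per-channel baseline mean
  seg <- data[, 901:1400]
  expect_equal(ep$data[1, , ], seg - rowMeans(seg[, 1:100]), tolerance = 1e-12)

  # events whose window spills over an edge are excluded
  ev2 <- rbind(ev, data.frame(sample = 1995L, onset_s = 3.99, series = 2L,
                              condition = "STD", test_series = FALSE))
  expect_equal(dim(epoch_recording(as_recording(data, 500, ev2))$data)[1], 1)

  # no fitting event: empty epoch set with a warning
  ev3 <- data.frame(sample = 10L, onset_s = 0.02, series = 2L,
                    condition = "STD", test_series = FALSE)
  expect_warning(ep0 <- epoch_recording(as_recording(data, 500, ev3)),
                 "no event")
  expect_equal(length(ep0$conditions), 0)
})

test_that("test series is excluded and the full protocol yields 300 epochs", {
  m <- small_model()
  sch <- make_schedule(seed = 6)    # default 4 x 100
  rec <- simulate_recording(sch, m$lf, m$atlas, pick_source_region(m),
                            noise = noise_config(0.5, 0), srate = 100,
                            seed = 6)
  ep <- epoch_recording(rec)
  expect_equal(length(ep$conditions), 300)
  expect_equal(sum(ep$conditions == "TGT"), 60)
  ep_all <- epoch_recording(rec, exclude_test_series = FALSE)
  expect_equal(length(ep_all$conditions), 400)
})

test_that("baseline mean is exactly zero after epoching", {
  m <- small_model()
  sch <- make_schedule(2, 12, 0.25, seed = 2)
  rec <- simulate_recording(sch, m$lf, m$atlas, pick_source_region(m),
                            srate = 250, seed = 8)
  ep <- epoch_recording(rec)
  b <- ep$times >= -0.2 & ep$times < 0
  for (i in seq_along(ep$conditions)) {
    expect_lt(max(abs(rowMeans(ep$data[i, , b]))), 1e-9)
  }
})

test_that("artifact rejection: thresholds, flat rule, monotonicity, conservation", {
  m <- small_model()
  sch <- make_schedule(2, 12, 0.25, seed = 2)
  rec <- simulate_recording(sch, m$lf, m$atlas, pick_source_region(m),
                            noise = noise_config(1, 0.5), srate = 250,
                            seed = 8)
  ep <- reject_artifacts(epoch_recording(rec))
  expect_true(all(ep$kept))               # clean synthetic data all kept

  # all-zero epochs are rejected as flat
  zep <- ep
  zep$data[] <- 0
  expect_false(any(reject_artifacts(zep)$kept))

  # lowering the peak-to-peak threshold never keeps more epochs
  thresholds <- c(200, 100, 50, 20, 10, 5)
  kept <- vapply(thresholds,
                 function(th) sum(reject_artifacts(ep, ptp_threshold = th)$kept),
                 0L)
  expect_true(all(diff(kept) <= 0))
  # kept + rejected = total at every threshold
  expect_true(all(vapply(thresholds, function(th) {
    e <- reject_artifacts(ep, ptp_threshold = th)
    sum(e$kept) + sum(!e$kept) == length(e$conditions)
  }, TRUE)))
})

test_that("epochs overlapping injected blinks are exactly the rejected set", {
  m <- small_model()
  sch <- make_schedule(2, 30, 0.2, seed = 9)
  rec <- simulate_recording(sch, m$lf, m$atlas, pick_source_region(m),
                            tgt_amplitude = 0, std_amplitude = 0,
                            noise = noise_config(0.5, 0), srate = 250,
                            seed = 9)
  rec <- inject_blinks(rec, rate = 20, amplitude = 400, seed = 10)
  ep <- reject_artifacts(epoch_recording(rec))

  # oracle: a 400 uV half-sine crosses the 150 uV threshold while its
  # template exceeds 150/400, i.e. in the central part of its 300 ms span;
  # an epoch is rejected iff its window contains such a sample
  srate <- 250
  blink_len <- round(0.3 * srate)
  template <- sin(pi * seq_len(blink_len) / blink_len)
  hot <- which(template * 400 > 150)
  hot_samples <- unlist(lapply(rec$meta$blink_samples,
                               function(o) o + hot - 1L))   # 0-based
  ev <- rec$events[!rec$events$test_series, ]
  starts <- ev$sample + round(-0.2 * srate)
  n_len <- 250
  fits <- starts >= 0 & starts + n_len <= ncol(rec$data)
  starts <- starts[fits]
  expected_bad <- vapply(starts, function(s) {
    any(hot_samples >= s & hot_samples < s + n_len)
  }, TRUE)
  expect_gt(sum(expected_bad), 0)
  expect_lt(sum(expected_bad), length(starts))
  expect_equal(!ep$kept, expected_bad)
})

test_that("averaging pools kept epochs per condition with 1/N variance", {
  # construct an epoch set of pure i.i.d. white noise directly
  n_ep <- 200; sigma <- 3
  set.seed(42)
  es <- structure(
    list(data = array(rnorm(n_ep * 2 * 100, sd = sigma), c(n_ep, 2, 100)),
         conditions = rep("TGT", n_ep), kept = rep(TRUE, n_ep),
         times = seq(0, 0.99, by = 0.01), window = c(-0.01, 0.99),
         baseline = c(-0.01, 0), srate = 100),
    class = "epoch_set")
  avg <- average_epochs(es, "TGT")
  expect_equal(avg$n_averaged, n_ep)
  # variance of the average is sigma^2 / N within 20%
  expect_equal(mean(avg$data^2), sigma^2 / n_ep, tolerance = 0.2)

  # two identical epochs average to themselves
  es2 <- es
  es2$data <- es$data[c(1, 1), , , drop = FALSE]
  es2$conditions <- c("STD", "STD"); es2$kept <- c(TRUE, TRUE)
  expect_equal(average_epochs(es2, "STD")$data, es$data[1, , ],
               tolerance = 1e-12)

  # condition filter and rejection mask are honored
  es$conditions[1:50] <- "STD"
  es$kept[1:10] <- FALSE
  expect_equal(average_epochs(es, "STD")$n_averaged, 40)
  expect_equal(average_epochs(es, "TGT")$n_averaged, 150)
  es$kept[] <- FALSE
  expect_error(average_epochs(es, "TGT"), "no kept epochs")
})

test_that("band-pass filter is zero-phase and removes out-of-band power", {
  t <- seq(0, 10 - 1 / 250, by = 1 / 250)
  x <- sin(2 * pi * 10 * t) + sin(2 * pi * 90 * t) + 5   # in-band + out-of-band + DC
  rec <- as_recording(rbind(x, x, x, x, x, x, x, x), 250,
                      data.frame(sample = integer(), onset_s = numeric(),
                                 series = integer(), condition = character(),
                                 test_series = logical()))
  out <- bandpass_filter(rec, 0.5, 40)$data[1, ]
  mid <- 500:2000
  # the 10 Hz component survives in phase (zero-phase filter), the rest goes
  expect_equal(out[mid], sin(2 * pi * 10 * t)[mid], tolerance = 0.05)
})
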