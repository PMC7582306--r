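test_that("bandpass filter passes in-band and rejects out-of-band tones", {
  fs <- 128
  t <- (0:(30 * fs - 1)) / fs
  mid <- seq(5 * fs, 25 * fs) # central region, clear of edge transients
  zero <- eeg_recording(cbind(A = rep(0, length(t))), fs)
  expect_true(all(bandpass_filter(zero, 0.5, 30)$data == 0))

  hi <- eeg_recording(cbind(A = sin(2 * pi * 50 * t)), fs)
  out <- bandpass_filter(hi, 0.5, 30)$data[mid, 1]
  expect_lt(sqrt(mean(out^2)), 0.1 * sqrt(0.5))

  inband <- eeg_recording(cbind(A = sin(2 * pi * 10 * t)), fs)
  out <- bandpass_filter(inband, 0.5, 30)$data[mid, 1]
  expect_equal(sqrt(mean(out^2)), sqrt(0.5), tolerance = 0.05)
})

test_that("bandpass filter validates the band against Nyquist", {
  rec <- eeg_recording(cbind(A = rnorm(256)), 128)
  expect_error(bandpass_filter(rec, 0.5, 70), "Nyquist|fs/2")
  expect_error(bandpass_filter(rec, 30, 0.5), "Nyquist|fs/2")
})

test_that("segmentation discards the trailing remainder", {
  fs <- 64
  rec <- eeg_recording(cbind(A = rnorm(60 * fs)), fs)
  expect_length(segment_windows(rec, 5), 12)
  rec12 <- eeg_recording(cbind(A = rnorm(12 * fs)), fs)
  w <- segment_windows(rec12, 5)
  expect_length(w, 2)
  expect_equal(attr(w, "t_start_s"), c(0, 5))
  expect_equal(nrow(w[[1]]), 5 * fs)
  rec3 <- eeg_recording(cbind(A = rnorm(3 * fs)), fs)
  expect_length(segment_windows(rec3, 5), 0)
})

test_that("band power matches closed-form and Parseval oracles on sinusoids", {
  fs <- 128
  t <- (0:(5 * fs - 1)) / fs
  x <- sin(2 * pi * 6 * t) # unit amplitude: total power 0.5
  expect_equal(band_power(x, fs, c(4, 7)), 0.5, tolerance = 0.05)
  # Parseval-style periodogram oracle on the same detrended window
  for (f0 in c(5, 6.5, 10, 11)) {
    y <- 1.7 * sin(2 * pi * f0 * t + 0.3)
    band <- if (f0 < 8) c(4, 7) else c(8, 12)
    expect_equal(band_power(y, fs, band),
                 fft_band_power(y - mean(y), fs, band[1], band[2]),
                 tolerance = 0.1 * fft_band_power(y, fs, band[1], band[2]))
  }
})

test_that("band power of degenerate windows is as expected", {
  fs <- 128
  expect_equal(band_power(rep(0, 5 * fs), fs, c(4, 7)), 0)
  ramp <- seq(0, 10, length.out = 5 * fs) # pure trend, removed by detrending
  expect_lt(band_power(ramp, fs, c(4, 7)), 1e-6)
  expect_lt(band_power(ramp, fs, c(8, 12)), 1e-6)
  expect_error(band_power(rnorm(fs), fs, c(4, 7)), "2 s")
})

test_that("white-noise theta:alpha band-power ratio approaches 3:4", {
  set.seed(42)
  fs <- 128
  ratios <- replicate(100, {
    x <- rnorm(5 * fs)
    band_power(x, fs, c(4, 7)) / band_power(x, fs, c(8, 12))
  })
  expect_equal(mean(ratios), 0.75, tolerance = 0.08)
})

test_that("per-window index is the mean theta over mean alpha ratio", {
  expect_equal(eeg_index_window(c(F4 = 1, C4 = 1), c(O1 = 1, O2 = 1)), 1)
  expect_equal(eeg_index_window(c(2, 2), c(0.5, 0.5)), 4)
  expect_true(is.na(eeg_index_window(c(1, 1), c(0, 0))))
})

test_that("outlier replacement follows the 3-SD rule with mean substitution", {
  s <- index_series(seq(0, by = 5, length.out = 31),
                    c(rep(1, 30), 10), 5, "x")
  # oracle: the 10.0 exceeds mean + 3 SD of the full series
  m <- mean(s$value); sd0 <- sd(s$value)
  expect_gt(10, m + 3 * sd0)
  r <- reject_outliers(s, 3)
  expect_equal(attr(r, "n_replaced"), 1L)
  expect_equal(r$value[31], 1)
  expect_true(r$flagged[31])

  const <- index_series(1:10 * 5, rep(2.5, 10), 5, "c")
  rc <- reject_outliers(const)
  expect_equal(attr(rc, "n_replaced"), 0L)
  expect_equal(rc$value, const$value)
})

test_that("a value exactly at mean + 3 SD is retained", {
  base <- c(rep(-1, 8), rep(1, 8))
  # solve for x with x == mean(c(base, x)) + 3 * sd(c(base, x))
  f <- function(x) x - mean(c(base, x)) - 3 * sd(c(base, x))
  x_star <- uniroot(f, c(1, 100), tol = 1e-12)$root
  s <- index_series(seq_along(c(base, x_star)) * 5, c(base, x_star), 5)
  r <- reject_outliers(s, 3)
  expect_equal(attr(r, "n_replaced"), 0L)
  # nudged past the boundary it is replaced
  s2 <- index_series(s$t_s, c(base, x_star * 1.05), 5)
  expect_equal(attr(reject_outliers(s2, 3), "n_replaced"), 1L)
})

test_that("moving-average smoothing is identity-preserving and low-pass", {
  const <- index_series(0:49 * 5, rep(3, 50), 5)
  expect_equal(smooth_index(const, 60)$value, rep(3, 50))

  imp <- index_series(0:49 * 5, c(rep(0, 25), 12, rep(0, 24)), 5)
  sm <- smooth_index(imp, 60) # 12-sample window
  expect_equal(sum(sm$value > 0.999), 12)
  expect_equal(max(sm$value), 1)

  alt <- index_series(0:99 * 5, rep(c(1, -1), 50), 5)
  sa <- smooth_index(alt, 60)
  expect_lt(max(abs(sa$value[20:80])), 0.1)
})

test_that("full pipeline recovers the closed-form ratio and workload contrast", {
  rec <- sinusoid_recording(theta_amp = 2, alpha_amp = 1, dur_s = 60)
  s <- compute_eeg_index_series(rec)
  expect_equal(mean(s$value), 4, tolerance = 0.1 * 4)
  expect_true(all(s$value[!s$flagged] > 0))

  # two-level workload: second half strictly larger mean index
  sched <- make_phase_schedule(c(30, 30, 30, 30, 30))
  prof <- generate_workload_profile(sched, c(0.1, 0.1, 0.1, 0.9, 0.9), 5)
  rec2 <- generate_eeg(prof, list(channels = c("F4", "C4", "O1", "O2")),
                       seed = 5)
  s2 <- compute_eeg_index_series(rec2)
  first <- mean(s2$value[s2$t_s < 75])
  second <- mean(s2$value[s2$t_s >= 75])
  expect_gt(second, first)
})

test_that("index series is invariant to global amplitude scaling", {
  prof <- flat_profile(0.5)
  rec <- generate_eeg(prof, list(channels = c("F4", "C4", "O1", "O2")),
                      seed = 2)
  scaled <- eeg_recording(rec$data * 3.7, rec$fs, rec$channels, rec$t0_s)
  s1 <- compute_eeg_index_series(rec)
  s2 <- compute_eeg_index_series(scaled)
  expect_equal(s2$value, s1$value, tolerance = 1e-6)
})

test_that("missing index channels raise a channel error", {
  rec <- eeg_recording(cbind(F4 = rnorm(640), C4 = rnorm(640),
                             O1 = rnorm(640)), 128)
  expect_error(compute_eeg_index_series(rec), "O2")
})

test_that("the estimator chain is stable on a stationary recording", {
  # constant workload with amplitude drift disabled: the residual variation
  # is the pipeline's own (filtering + Welch + smoothing) estimation noise
  cvs <- vapply(1:5, function(seed) {
    rec <- generate_eeg(flat_profile(0.5),
                        list(channels = c("F4", "C4", "O1", "O2"),
                             drift_sd = 0), seed)
    s <- compute_eeg_index_series(rec)
    v <- s$value[!s$flagged]
    sd(v) / mean(v)
  }, numeric(1))
  expect_true(all(cvs < 0.3))
})
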