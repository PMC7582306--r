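# Generators: determinism, stream/schedule consistency and statistical
# encoding of the latent workload.

test_that("every generator is a pure function of (config, seed)", {
  prof <- flat_profile(0.5)
  expect_identical(generate_eeg(prof, seed = 4), generate_eeg(prof, seed = 4))
  expect_identical(generate_gaze(prof, seed = 4), generate_gaze(prof, seed = 4))
  sched <- short_schedule()
  expect_identical(generate_uav_logs(sched, seed = 4, profile = prof),
                   generate_uav_logs(sched, seed = 4, profile = prof))
  expect_identical(generate_clicks(prof, seed = 4),
                   generate_clicks(prof, seed = 4))
  expect_false(identical(generate_clicks(prof, seed = 4),
                         generate_clicks(prof, seed = 5)))
})

test_that("per-stream sub-seeds keep streams independent of each other", {
  cfg1 <- short_config(seed = 9)
  cfg2 <- short_config(seed = 9, gaze = list(fs = 30))
  b1 <- simulate_session(cfg1)
  b2 <- simulate_session(cfg2)
  # changing the gaze stream's settings must not perturb the EEG stream
  expect_identical(b1$eeg, b2$eeg)
  expect_identical(b1$clicks, b2$clicks)
})

test_that("all streams lie inside the schedule span", {
  b <- simulate_session(short_config(seed = 2))
  span <- schedule_span(b$schedule)
  eeg_t <- b$eeg$t0_s + c(0, (nrow(b$eeg$data) - 1) / b$eeg$fs)
  for (rng in list(eeg_t, range(b$gaze$t_s), range(b$uav_logs$t_s),
                   range(b$clicks$t_s))) {
    expect_gte(rng[1], span[1])
    expect_lte(rng[2], span[2])
  }
})

test_that("theta and alpha encodings are monotone in workload (FFT oracle)", {
  sched <- make_phase_schedule(c(30, 30, 30, 30, 30))
  cfg <- quiet_eeg(channels = c("F4", "C4", "O1", "O2"))
  power_at <- function(w, band) {
    prof <- generate_workload_profile(sched, rep(w, 5), 5)
    rec <- generate_eeg(prof, cfg, seed = 1)
    c(fft_band_power(rec$data[, "F4"], rec$fs, band[1], band[2]),
      fft_band_power(rec$data[, "O1"], rec$fs, band[1], band[2]))
  }
  levels <- c(0, 0.3, 0.6, 1)
  theta <- vapply(levels, function(w) power_at(w, c(4, 7))[1], numeric(1))
  alpha <- vapply(levels, function(w) power_at(w, c(8, 12))[2], numeric(1))
  expect_true(all(diff(theta) > 0))
  expect_true(all(diff(alpha) < 0))
})

test_that("noise-free EEG is stationary under constant workload", {
  prof <- flat_profile(0.5)
  rec <- generate_eeg(prof, quiet_eeg(channels = c("F4", "C4", "O1", "O2")),
                      seed = 1)
  span1 <- rec$data[1:(60 * rec$fs), "F4"]
  span2 <- rec$data[(240 * rec$fs):(300 * rec$fs - 1), "F4"]
  p1 <- fft_band_power(span1, rec$fs, 4, 7)
  p2 <- fft_band_power(span2, rec$fs, 4, 7)
  expect_equal(p1, p2, tolerance = 0.02 * p1)
})

test_that("missing required EEG channels are a config error", {
  expect_error(generate_eeg(flat_profile(), list(channels = c("F4", "C4")),
                            seed = 1), "O1")
})

test_that("gaze dropout bursts hit the configured invalid fraction", {
  sched <- make_phase_schedule(c(10, 50, 50, 50, 10))
  prof <- generate_workload_profile(sched, rep(0.5, 5))
  st <- generate_gaze(prof, clean_gaze(dropout_fraction = 0.1, fs = 60),
                      seed = 8)
  expect_gte(nrow(st), 10000)
  frac <- mean(!st$left_valid & !st$right_valid)
  expect_equal(frac, 0.1, tolerance = 0.2) # 0.1 +/- 0.02
})

test_that("scanpath transition matrices are valid and reach their limits", {
  for (tau in c(0, 0.3, 2)) {
    p <- scan_transition_matrix(9, tau)
    expect_equal(rowSums(p), rep(1, 9))
    expect_true(all(diag(p) == 0))
  }
  expect_equal(scanpath_conditional_entropy(scan_transition_matrix(9, 0)), 0)
  expect_equal(scanpath_conditional_entropy(scan_transition_matrix(9, 1e6)),
               log2(8), tolerance = 1e-3)
})

test_that("UAV fleet growth follows the configured per-phase counts", {
  sched <- make_phase_schedule()
  logs <- generate_uav_logs(sched, seed = 1)
  n_active <- function(t) length(unique(logs$uav_id[logs$t_s <= t]))
  expect_equal(n_active(310), 3)
  expect_equal(n_active(910), 6)
  expect_equal(n_active(1510), 9)
  expect_error(generate_uav_logs(sched, list(counts = c(6, 3, 9)), 1),
               "non-decreasing")
  expect_error(generate_uav_logs(sched, list(counts = c(-1, 3, 9)), 1),
               "non-negative")
})

test_that("quiet UAV logs score a zero task index once assigned", {
  sched <- short_schedule()
  cfg <- list(nav_rate_per_min = 0, comm_rate_per_min = 0,
              fuel_rate_per_min = 0, hold_rate_per_min = 0,
              rate_gain_per_min = 0, assign_delay_mean_s = 0,
              sensor_delay_mean_s = 0)
  logs <- generate_uav_logs(sched, cfg, seed = 3)
  s <- task_index_series(logs, t_range = schedule_span(sched))
  expect_true(all(s$value == 0))
})

test_that("degradation episodes match the Poisson expectation", {
  sched <- make_phase_schedule()
  r <- 0.05 # events per UAV-minute; 9 UAVs x 30 min -> 13.5 expected
  cfg <- list(counts = c(9, 9, 9), log_step_s = 1,
              nav_rate_per_min = r, comm_rate_per_min = 0,
              fuel_rate_per_min = 0, hold_rate_per_min = 0,
              rate_gain_per_min = 0, recover_mean_s = 60,
              assign_delay_mean_s = 0, sensor_delay_mean_s = 0)
  onsets <- vapply(1:20, function(seed) {
    logs <- generate_uav_logs(sched, cfg, seed)
    sum(vapply(unique(logs$uav_id), function(u) {
      nav <- logs$nav_acc_m[logs$uav_id == u]
      degraded <- nav > 10
      sum(diff(degraded) > 0) + degraded[1]
    }, numeric(1)))
  }, numeric(1))
  expected <- 9 * 30 * r
  # onset counting from the logs slightly undercounts merged/short episodes
  expect_equal(mean(onsets), expected, tolerance = 0.25 * expected)
})

test_that("click process matches its Poisson rate", {
  prof0 <- flat_profile(0)
  expect_equal(nrow(generate_clicks(prof0, list(base_hz = 0, gain_hz = 0),
                                    seed = 1)), 0)
  sched <- make_phase_schedule(c(120, 120, 120, 120, 120))
  prof <- generate_workload_profile(sched, rep(0, 5))
  for (seed in 1:5) {
    n <- nrow(generate_clicks(prof, list(base_hz = 0.5, gain_hz = 0), seed))
    expect_lt(abs(n - 300), 3 * sqrt(300))
  }
  expect_error(generate_clicks(prof, list(base_hz = -1), 1), "non-negative")
})

test_that("subjective ratings stay on their scales with rising workload", {
  r <- generate_ratings(seed = 2)
  expect_equal(r$phase, mission_phases())
  expect_true(all(r$mwl >= 0 & r$mwl <= 10))
  expect_true(all(r$sa >= 0 & r$sa <= 10))
})

test_that("session bundles validate their configuration", {
  expect_error(session_config(levels = c(2, 0.2, 0.5, 0.9, 0.1)), "levels")
  expect_error(session_config(eeg = list(fs = 32)), "eeg.fs")
  expect_error(session_config(uav = list(counts = c(-3, 6, 9))), "uav.counts")
})
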