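# Shared fixtures: short sessions and hand-built streams, generated in code.

# A short five-phase schedule long enough for 60-s entropy/smoothing windows
# in every phase.
short_schedule <- function() {
  make_phase_schedule(c(60, 120, 120, 120, 90))
}

short_config <- function(seed = 1L, ...) {
  session_config(schedule = short_schedule(), seed = seed, ...)
}

# Constant-workload profile over a given schedule.
flat_profile <- function(level = 0.5, schedule = short_schedule(),
                         grid_step_s = 5) {
  generate_workload_profile(schedule, rep(level, 5), grid_step_s)
}

# Noise-free EEG generator settings: only the workload-driven narrowband
# components remain.
quiet_eeg <- function(...) {
  utils::modifyList(
    list(noise_scale = 0, white_scale = 0, artifact_rate = 0, drift_sd = 0),
    list(...))
}

# Deterministic-scanpath gaze settings (no jitter, no dropout, no blinks).
clean_gaze <- function(...) {
  utils::modifyList(
    list(jitter_sd = 0, dropout_fraction = 0, mono_dropout = 0,
         blink_rate_hz = 0, eye_noise_sd = 0, entropy_drift_sd = 0),
    list(...))
}

# A recording holding pure sinusoids: theta_amp at theta_hz on F4/C4 and
# alpha_amp at alpha_hz on O1/O2 (zeros elsewhere).
sinusoid_recording <- function(theta_amp = 2, alpha_amp = 1, dur_s = 60,
                               fs = 128, theta_hz = 6, alpha_hz = 10) {
  t <- (0:(dur_s * fs - 1)) / fs
  chans <- c("F4", "C4", "O1", "O2")
  x <- cbind(F4 = theta_amp * sin(2 * pi * theta_hz * t),
             C4 = theta_amp * sin(2 * pi * theta_hz * t + 1),
             O1 = alpha_amp * sin(2 * pi * alpha_hz * t),
             O2 = alpha_amp * sin(2 * pi * alpha_hz * t + 2))
  eeg_recording(x, fs, chans)
}

# Independent periodogram band power (Parseval-consistent): mean squared
# contribution of the DFT bins inside [low, high] Hz. Used as the FFT oracle
# against the Welch-based pipeline.
fft_band_power <- function(x, fs, low, high) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n^2
  f <- (0:(n - 1)) * fs / n
  half <- f <= fs / 2
  idx <- which(half & f >= low & f <= high)
  p <- sp[idx]
  dbl <- ifelse(idx - 1 == 0 | (n %% 2 == 0 & idx - 1 == n / 2), 1, 2)
  sum(p * dbl)
}

# Brute-force one-way ANOVA from the sum-of-squares decomposition.
anova_oracle <- function(groups) {
  all_v <- unlist(groups)
  gm <- mean(all_v)
  n_i <- vapply(groups, length, 1L)
  m_i <- vapply(groups, mean, numeric(1))
  ssb <- sum(n_i * (m_i - gm)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df1 <- length(groups) - 1L
  df2 <- sum(n_i) - length(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(F = f, df1 = df1, df2 = df2, p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# Studentized-range (Tukey) decisions from first principles.
tukey_oracle <- function(groups, alpha = 0.05) {
  k <- length(groups)
  n_i <- vapply(groups, length, 1L)
  m_i <- vapply(groups, mean, numeric(1))
  df2 <- sum(n_i) - k
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / df2
  pairs <- utils::combn(k, 2)
  sig <- logical(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(msw / 2 * (1 / n_i[a] + 1 / n_i[b]))
    q <- abs(m_i[a] - m_i[b]) / se
    sig[j] <- stats::ptukey(q, k, df2, lower.tail = FALSE) < alpha
  }
  sig
}

# Term-by-term evaluation of the conditional-entropy formula, written
# independently of the package implementation.
entropy_oracle <- function(counts) {
  total <- sum(counts)
  h <- 0
  for (i in seq_len(nrow(counts))) {
    ri <- sum(counts[i, ])
    if (ri == 0) next
    px <- ri / total
    inner <- 0
    for (j in seq_len(ncol(counts))) {
      pij <- counts[i, j] / ri
      if (pij > 0) inner <- inner + pij * log2(pij)
    }
    h <- h - px * inner
  }
  h
}
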