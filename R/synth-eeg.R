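#' Default synthetic EEG generator settings
#'
#' Amplitudes are in microvolts. The workload level w in `[0, 1]` modulates
#' two narrowband components linearly: a theta-band (5.5 Hz) sinusoid on F4
#' and C4 with amplitude `theta_base + theta_gain * w`, and an alpha-band
#' (10 Hz) sinusoid on O1 and O2 with amplitude
#' `alpha_base * (1 - alpha_suppression * w)` — the frontal/central theta
#' increase and occipital alpha suppression that the spectral workload index
#' is built on. The background is `1/f^beta` noise plus white noise on every
#' channel, and occasional high-amplitude artifact bumps (about 5 per default
#' session at the default rate) exercise the outlier-replacement stage.
#' Slow multiplicative amplitude drift (independent Ornstein-Uhlenbeck
#' processes on the log theta and log alpha amplitudes, standard deviation
#' `drift_sd`, correlation time `drift_tau_s`) emulates the nonstationarity
#' of real recordings; set `drift_sd = 0` for a strictly
#' workload-deterministic signal.
#'
#' @return Named list of generator parameters.
#' @export
eeg_defaults <- function() {
  list(
    fs = 128,
    channels = c("F4", "Fz", "F3", "FC1", "FC2", "C3", "C4", "CP1", "CP2",
                 "T7", "T8", "P3", "Pz", "P4", "O1", "O2"),
    theta_hz = 5.5, alpha_hz = 10,
    theta_base = 4, theta_gain = 1.6,
    alpha_base = 10, alpha_suppression = 0.3,
    noise_scale = 8, noise_exponent = 1, white_scale = 2,
    drift_sd = 0.24, drift_tau_s = 8,
    artifact_rate = 0.002, artifact_amp = 120, artifact_width_s = 0.05
  )
}

# Internal: stationary Ornstein-Uhlenbeck (AR(1)) drift process sampled at
# times t, with correlation time tau_s and stationary standard deviation sd.
ou_drift <- function(t, tau_s, sd) {
  n <- length(t)
  if (sd <= 0 || n == 0L) return(numeric(n))
  x <- numeric(n)
  x[1L] <- stats::rnorm(1, 0, sd)
  if (n > 1L) {
    a <- exp(-diff(t) / tau_s)
    innov <- stats::rnorm(n - 1L)
    for (k in 2:n) {
      x[k] <- a[k - 1L] * x[k - 1L] + sd * sqrt(1 - a[k - 1L]^2) * innov[k - 1L]
    }
  }
  x
}

# Internal: unit-variance 1/f^beta ("pink" for beta = 1) noise of length n,
# generated by spectrally shaping white Gaussian noise.
pink_noise <- function(n, exponent = 1) {
  if (n < 2L) return(stats::rnorm(n))
  w <- stats::fft(stats::rnorm(n))
  k <- 0:(n - 1L)
  f <- pmin(k, n - k) # two-sided frequency index (cycles per record)
  s <- ifelse(f > 0, f^(-exponent / 2), 0) # DC removed
  x <- Re(stats::fft(w * s, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate a synthetic multi-channel EEG recording
#'
#' Pure function of `(profile, cfg, seed)`: calling it twice with the same
#' arguments yields bit-identical recordings. See [eeg_defaults()] for the
#' signal model. The channel set must include F4, C4, O1 and O2 (the four
#' channels the workload index uses).
#'
#' @param profile A `workload_profile`.
#' @param cfg Generator settings; entries override [eeg_defaults()].
#' @param seed Integer random seed.
#' @return An `eeg_recording`.
#' @export
generate_eeg <- function(profile, cfg = list(), seed = 1L) {
  stopifnot(inherits(profile, "workload_profile"))
  cfg <- utils::modifyList(eeg_defaults(), cfg)
  req <- c("F4", "C4", "O1", "O2")
  if (!all(req %in% cfg$channels)) {
    stop("eeg config: channels must include ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (cfg$fs < 64) {
    stop("eeg config: sampling rate must be at least 64 Hz", call. = FALSE)
  }
  set.seed(as.integer(seed))
  span <- schedule_span(profile$schedule)
  n <- floor((span[2L] - span[1L]) * cfg$fs)
  t <- span[1L] + (0:(n - 1L)) / cfg$fs
  w <- workload_at(profile, t)
  theta_amp <- cfg$theta_base + cfg$theta_gain * w
  alpha_amp <- cfg$alpha_base * pmax(0, 1 - cfg$alpha_suppression * w)
  if (cfg$drift_sd > 0) {
    # slow amplitude drift, simulated on the coarse profile grid and
    # interpolated to sample times
    tg <- profile$grid_s
    d_theta <- ou_drift(tg, cfg$drift_tau_s, cfg$drift_sd)
    d_alpha <- ou_drift(tg, cfg$drift_tau_s, cfg$drift_sd)
    theta_amp <- theta_amp * exp(stats::approx(tg, d_theta, xout = t,
                                               rule = 2)$y)
    alpha_amp <- alpha_amp * exp(stats::approx(tg, d_alpha, xout = t,
                                               rule = 2)$y)
  }
  k <- length(cfg$channels)
  x <- matrix(0, n, k, dimnames = list(NULL, cfg$channels))
  for (j in seq_len(k)) {
    ch <- cfg$channels[j]
    bg <- cfg$noise_scale * pink_noise(n, cfg$noise_exponent) +
      cfg$white_scale * stats::rnorm(n)
    phase <- stats::runif(1, 0, 2 * pi)
    comp <- 0
    if (ch %in% c("F4", "C4")) {
      comp <- theta_amp * sin(2 * pi * cfg$theta_hz * t + phase)
    } else if (ch %in% c("O1", "O2")) {
      comp <- alpha_amp * sin(2 * pi * cfg$alpha_hz * t + phase)
    }
    x[, j] <- bg + comp
  }
  # broadband artifact bumps (blink/movement-like), frontal-dominant
  n_art <- stats::rpois(1, cfg$artifact_rate * (span[2L] - span[1L]))
  if (n_art > 0) {
    art_t <- stats::runif(n_art, span[1L], span[2L])
    art_a <- stats::rnorm(n_art, cfg$artifact_amp, cfg$artifact_amp / 6)
    topo <- ifelse(grepl("^(F|FC)", cfg$channels), 1, 0.6)
    for (a in seq_len(n_art)) {
      lo <- max(1L, floor((art_t[a] - span[1L] - 6 * cfg$artifact_width_s) * cfg$fs))
      hi <- min(n, ceiling((art_t[a] - span[1L] + 6 * cfg$artifact_width_s) * cfg$fs))
      idx <- lo:hi
      bump <- art_a[a] * exp(-0.5 * ((t[idx] - art_t[a]) / cfg$artifact_width_s)^2)
      x[idx, ] <- x[idx, ] + outer(bump, topo)
    }
  }
  eeg_recording(x, cfg$fs, cfg$channels, span[1L])
}
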