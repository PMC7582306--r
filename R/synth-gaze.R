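#' Default synthetic gaze generator settings
#'
#' The scanpath is a first-order Markov chain over the ROI centres of
#' `roi_layout`: from region i the preferred next region is the next tile in
#' a fixed cyclic scan, and a softmax temperature controls how often the
#' operator deviates from it. At temperature 0 the scan is a deterministic
#' cycle (entropy 0); at high temperature transitions approach uniformity
#' (entropy `log2(n - 1)`). By default the temperature at workload w is
#' chosen (by inverting the chain's analytic conditional entropy, see
#' [scan_temperature_for_entropy()]) so that the scanpath entropy is linear
#' in w between `entropy_bits[1]` and `entropy_bits[2]` — a scanning pattern
#' whose disorder tracks workload directly. Setting `temp_base`/`temp_gain`
#' switches to an affine temperature law `temp_base + temp_gain * w`
#' instead. A slow Ornstein-Uhlenbeck drift on the entropy target
#' (`entropy_drift_sd` bits, correlation time `drift_tau_s`) emulates
#' attention-state nonstationarity, independently of the EEG generator's
#' drift; set it to 0 for a strictly workload-deterministic scanpath. Dwell
#' durations are exponential. Tracking dropout comes in contiguous bursts
#' (both eyes invalid) with a geometric duration, plus independent per-eye
#' single-sample dropouts and short blinks.
#'
#' @return Named list of generator parameters.
#' @export
gaze_defaults <- function() {
  list(
    fs = 60,
    roi_layout = default_roi_layout(),
    entropy_bits = c(1.2, 2.2), entropy_exponent = 1.6,
    entropy_drift_sd = 0.52, drift_tau_s = 8,
    temp_base = NULL, temp_gain = NULL,
    dwell_mean_s = 0.5,
    jitter_sd = 0.02,
    eye_offset = 0.006, eye_noise_sd = 0.002,
    dropout_fraction = 0.02, dropout_burst_s = 0.3,
    mono_dropout = 0.01,
    blink_rate_hz = 0.2, blink_dur_s = 0.12
  )
}

#' Markov scanpath transition matrix at a given temperature
#'
#' Softmax over a cyclic preference: from state i the preferred target is
#' `i %% n + 1`; off-diagonal weights are `exp(pref / temperature)` with
#' `pref = 1` for the preferred target and 0 otherwise. Temperature 0 is the
#' deterministic cycle; temperature `Inf` is uniform over the `n - 1`
#' non-self targets.
#'
#' @param n Number of regions (states).
#' @param temperature Non-negative softmax temperature.
#' @return An `n x n` row-stochastic matrix with zero diagonal.
#' @export
scan_transition_matrix <- function(n, temperature) {
  stopifnot(n >= 2, temperature >= 0)
  p <- matrix(0, n, n)
  for (i in seq_len(n)) {
    pref <- i %% n + 1L
    if (temperature <= 0) {
      p[i, pref] <- 1
    } else {
      w <- exp((as.numeric(seq_len(n) == pref) - 1) / temperature)
      w[i] <- 0
      p[i, ] <- w / sum(w)
    }
  }
  p
}

#' Analytic conditional entropy of a stationary Markov scanpath
#'
#' Entropy (bits) of the next-state distribution weighted by the stationary
#' distribution — the population value that the empirical windowed visual
#' entropy converges to for long windows.
#'
#' @param p Row-stochastic transition matrix.
#' @param stationary Optional stationary distribution; computed from the
#'   leading eigenvector of `t(p)` when omitted.
#' @return Entropy in bits.
#' @export
scanpath_conditional_entropy <- function(p, stationary = NULL) {
  if (is.null(stationary)) {
    e <- eigen(t(p))
    i <- which.min(abs(e$values - 1))
    v <- Re(e$vectors[, i])
    stationary <- v / sum(v)
  }
  row_h <- apply(p, 1L, function(q) {
    q <- q[q > 0]
    -sum(q * log2(q))
  })
  sum(stationary * row_h)
}

#' Softmax temperature realizing a target scanpath entropy
#'
#' Inverts the analytic conditional entropy of the cyclic-preference
#' scanpath chain of [scan_transition_matrix()] (whose stationary
#' distribution is uniform by symmetry, so the conditional entropy equals
#' the per-row entropy). Used by the gaze generator to encode workload
#' linearly in scanpath entropy.
#'
#' @param n Number of regions (at least 3 for a non-trivial inversion).
#' @param target_bits Target conditional entropy in bits, in
#'   `[0, log2(n - 1))`.
#' @return The (non-negative) softmax temperature.
#' @export
scan_temperature_for_entropy <- function(n, target_bits) {
  stopifnot(n >= 2, target_bits >= 0)
  if (target_bits <= 1e-9) return(0)
  h_max <- log2(n - 1)
  if (target_bits >= h_max - 1e-9) {
    stop(sprintf("scanpath entropy target must be below log2(n - 1) = %.3f bits",
                 h_max), call. = FALSE)
  }
  row_entropy <- function(tau) {
    e <- exp(-1 / tau)
    if (e == 0) return(0)
    p1 <- 1 / (1 + (n - 2) * e)
    p0 <- e * p1
    h <- -p1 * log2(p1)
    if (n > 2 && p0 > 0) h <- h - (n - 2) * p0 * log2(p0)
    h
  }
  stats::uniroot(function(tau) row_entropy(tau) - target_bits,
                 lower = 1e-3, upper = 1e3, tol = 1e-10)$root
}

#' Generate a synthetic binocular gaze stream
#'
#' Pure function of `(profile, cfg, seed)`. Samples follow the Markov
#' scanpath of [scan_transition_matrix()] over the ROI centres with Gaussian
#' jitter; the temperature is evaluated from the workload profile at each
#' dwell onset. Dropout bursts, blinks and monocular dropouts mark samples
#' invalid (coordinates `NA`).
#'
#' @param profile A `workload_profile`.
#' @param cfg Generator settings; entries override [gaze_defaults()].
#' @param seed Integer random seed.
#' @return A `gaze_stream` data frame with columns `t_s`, `left_x`, `left_y`,
#'   `left_valid`, `right_x`, `right_y`, `right_valid`, `blink`.
#' @export
generate_gaze <- function(profile, cfg = list(), seed = 1L) {
  stopifnot(inherits(profile, "workload_profile"))
  cfg <- utils::modifyList(gaze_defaults(), cfg)
  layout <- roi_layout(as.data.frame(cfg$roi_layout))
  if (cfg$fs < 10) {
    stop("gaze config: sampling rate must be at least 10 Hz", call. = FALSE)
  }
  set.seed(as.integer(seed))
  span <- schedule_span(profile$schedule)
  n <- floor((span[2L] - span[1L]) * cfg$fs)
  t <- span[1L] + (0:(n - 1L)) / cfg$fs
  n_roi <- nrow(layout)
  centers <- roi_centers(layout)

  # slow drift of the scanpath-entropy target (attention nonstationarity)
  drift_at <- function(tt) 0
  if (is.null(cfg$temp_base) && cfg$entropy_drift_sd > 0) {
    tg <- profile$grid_s
    d <- ou_drift(tg, cfg$drift_tau_s, cfg$entropy_drift_sd)
    drift_at <- function(tt) stats::approx(tg, d, xout = tt, rule = 2)$y
  }
  h_cap <- if (n_roi > 2) log2(n_roi - 1) - 0.05 else 0
  # dwell-by-dwell scanpath; transition matrices cached per (level, drift)
  # key, with the drift quantized to 0.02 bits to bound the cache
  temp_for <- function(w, dq) {
    if (!is.null(cfg$temp_base)) {
      cfg$temp_base + if (is.null(cfg$temp_gain)) 0 else cfg$temp_gain * w
    } else {
      target <- cfg$entropy_bits[1L] +
        diff(cfg$entropy_bits) * w^cfg$entropy_exponent + dq
      scan_temperature_for_entropy(n_roi, min(max(target, 0), h_cap))
    }
  }
  pmats <- list()
  pmat_for <- function(w, tt) {
    dq <- round(drift_at(tt) / 0.02) * 0.02
    key <- sprintf("%.3f|%.2f", w, dq)
    if (is.null(pmats[[key]])) {
      pmats[[key]] <<- scan_transition_matrix(n_roi, temp_for(w, dq))
    }
    pmats[[key]]
  }
  n_dwell_guess <- ceiling((span[2L] - span[1L]) / cfg$dwell_mean_s * 1.5) + 16L
  dw_start <- numeric(n_dwell_guess)
  dw_roi <- integer(n_dwell_guess)
  cur_t <- span[1L]
  cur_roi <- 1L
  m <- 0L
  while (cur_t < span[2L]) {
    m <- m + 1L
    if (m > length(dw_start)) {
      dw_start <- c(dw_start, numeric(length(dw_start)))
      dw_roi <- c(dw_roi, integer(length(dw_roi)))
    }
    dw_start[m] <- cur_t
    dw_roi[m] <- cur_roi
    dur <- max(1 / cfg$fs, stats::rexp(1, 1 / cfg$dwell_mean_s))
    cur_t <- cur_t + dur
    if (n_roi > 1L) {
      t_eval <- min(cur_t, span[2L])
      pr <- pmat_for(workload_at(profile, t_eval), t_eval)[cur_roi, ]
      cur_roi <- sample.int(n_roi, 1L, prob = pr)
    }
  }
  dw_start <- dw_start[seq_len(m)]
  dw_roi <- dw_roi[seq_len(m)]
  roi_idx <- dw_roi[findInterval(t, dw_start)]

  x <- centers[roi_idx, "x"] + stats::rnorm(n, 0, cfg$jitter_sd)
  y <- centers[roi_idx, "y"] + stats::rnorm(n, 0, cfg$jitter_sd)

  # binocular dropout bursts: two-state chain built from geometric run lengths
  invalid <- rep(FALSE, n)
  frac <- cfg$dropout_fraction
  if (frac > 0) {
    p_exit <- min(1, 1 / (cfg$dropout_burst_s * cfg$fs))
    p_enter <- min(1, p_exit * frac / (1 - frac))
    pos <- 1L
    state_invalid <- stats::runif(1) < frac
    while (pos <= n) {
      p_leave <- if (state_invalid) p_exit else p_enter
      len <- 1L + stats::rgeom(1, p_leave)
      hi <- min(n, pos + len - 1L)
      if (state_invalid) invalid[pos:hi] <- TRUE
      pos <- hi + 1L
      state_invalid <- !state_invalid
    }
  }
  # blinks: short both-eye closures
  blink <- rep(FALSE, n)
  if (cfg$blink_rate_hz > 0) {
    n_blink <- stats::rpois(1, cfg$blink_rate_hz * (span[2L] - span[1L]))
    if (n_blink > 0) {
      bt <- stats::runif(n_blink, span[1L], span[2L])
      for (b in bt) {
        blink[t >= b & t < b + cfg$blink_dur_s] <- TRUE
      }
    }
  }
  both_invalid <- invalid | blink
  left_valid <- !both_invalid & stats::runif(n) >= cfg$mono_dropout
  right_valid <- !both_invalid & stats::runif(n) >= cfg$mono_dropout

  left_x <- ifelse(left_valid, x - cfg$eye_offset +
                     stats::rnorm(n, 0, cfg$eye_noise_sd), NA_real_)
  left_y <- ifelse(left_valid, y + stats::rnorm(n, 0, cfg$eye_noise_sd),
                   NA_real_)
  right_x <- ifelse(right_valid, x + cfg$eye_offset +
                      stats::rnorm(n, 0, cfg$eye_noise_sd), NA_real_)
  right_y <- ifelse(right_valid, y + stats::rnorm(n, 0, cfg$eye_noise_sd),
                    NA_real_)

  out <- data.frame(
    t_s = t,
    left_x = left_x, left_y = left_y, left_valid = left_valid,
    right_x = right_x, right_y = right_y, right_valid = right_valid,
    blink = blink
  )
  class(out) <- c("gaze_stream", "data.frame")
  out
}
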