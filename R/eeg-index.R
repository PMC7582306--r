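#' Multi-channel EEG recording
#'
#' Container for a fixed-rate, multi-channel voltage recording with 10-20
#' system channel labels. Voltages are in microvolts.
#'
#' @param data Numeric matrix, one column per channel, one row per sample.
#' @param fs Sampling rate in Hz. Must exceed twice the 30 Hz top analysis
#'   band, i.e. at least 64 Hz in practice.
#' @param channels Character vector of channel labels (10-20 names); defaults
#'   to `colnames(data)`.
#' @param t0_s Start time of the first sample, seconds from session start.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, fs, channels = colnames(data), t0_s = 0) {
  data <- as.matrix(data)
  if (!is.numeric(data)) {
    stop("eeg: data must be a numeric matrix", call. = FALSE)
  }
  if (is.null(channels) || length(channels) != ncol(data)) {
    stop("eeg: one channel label per data column is required", call. = FALSE)
  }
  if (anyDuplicated(channels)) {
    stop("eeg: channel labels must be unique", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 60) {
    stop("eeg: sampling rate must exceed twice the 30 Hz analysis band",
         call. = FALSE)
  }
  colnames(data) <- channels
  structure(
    list(data = data, fs = as.numeric(fs), channels = as.character(channels),
         t0_s = as.numeric(t0_s)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("eeg_recording: %d channels x %d samples @ %g Hz (%.1f s from t0 = %g s)\n",
              ncol(x$data), nrow(x$data), x$fs, nrow(x$data) / x$fs, x$t0_s))
  cat("  channels:", paste(x$channels, collapse = " "), "\n")
  invisible(x)
}

# Internal: keep only the named channels (order preserved as requested).
subset_channels <- function(rec, channels) {
  missing <- setdiff(channels, rec$channels)
  if (length(missing)) {
    stop("eeg: required channel(s) missing from recording: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  eeg_recording(rec$data[, channels, drop = FALSE], rec$fs, channels, rec$t0_s)
}

#' Frequency band definition
#'
#' @param name Band name.
#' @param low_hz,high_hz Band edges in Hz, `0 < low < high`.
#' @return A `band_definition` list.
#' @export
band_definition <- function(name, low_hz, high_hz) {
  if (!is.numeric(low_hz) || !is.numeric(high_hz) ||
      low_hz <= 0 || high_hz <= low_hz) {
    stop("band: need 0 < low_hz < high_hz", call. = FALSE)
  }
  structure(list(name = name, low_hz = low_hz, high_hz = high_hz),
            class = "band_definition")
}

#' Default analysis bands: theta 4-7 Hz and alpha 8-12 Hz
#' @return Named list of two `band_definition`s.
#' @export
default_bands <- function() {
  list(theta = band_definition("theta", 4, 7),
       alpha = band_definition("alpha", 8, 12))
}

#' Zero-phase Butterworth bandpass filter
#'
#' 4th-order Butterworth applied forward and backward (`signal::filtfilt`),
#' giving a zero-phase band-limited copy of every channel. Length is
#' preserved.
#'
#' @param rec An `eeg_recording`.
#' @param low_hz,high_hz Passband edges in Hz; must satisfy
#'   `0 < low < high < fs/2`.
#' @param order Filter order (default 4).
#' @return A filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, low_hz = 0.5, high_hz = 30, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < rec$fs / 2)) {
    stop("bandpass: band must satisfy 0 < low < high < fs/2", call. = FALSE)
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / (rec$fs / 2), type = "pass")
  filtered <- apply(rec$data, 2L, function(x) signal::filtfilt(bf, x))
  eeg_recording(filtered, rec$fs, rec$channels, rec$t0_s)
}

#' Cut a recording into fixed-length non-overlapping windows
#'
#' Contiguous windows of `win_s` seconds; a trailing remainder shorter than
#' one window is discarded.
#'
#' @param rec An `eeg_recording`.
#' @param win_s Window length in seconds (default 5).
#' @return A list of numeric matrices (one per window, channels in columns),
#'   with attribute `t_start_s` giving each window's start time.
#' @export
segment_windows <- function(rec, win_s = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!is.numeric(win_s) || length(win_s) != 1L || win_s <= 0) {
    stop("segment: win_s must be a positive scalar", call. = FALSE)
  }
  nwin_samp <- floor(win_s * rec$fs)
  n_windows <- floor(nrow(rec$data) / nwin_samp)
  out <- vector("list", n_windows)
  for (i in seq_len(n_windows)) {
    rows <- ((i - 1L) * nwin_samp + 1L):(i * nwin_samp)
    out[[i]] <- rec$data[rows, , drop = FALSE]
  }
  attr(out, "t_start_s") <- rec$t0_s + (seq_len(n_windows) - 1L) * win_s
  attr(out, "win_s") <- win_s
  out
}

# Internal: remove the best-fitting straight line from a vector.
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2L) return(x - mean(x))
  t <- seq_len(n)
  fit <- stats::lm.fit(cbind(1, t), x)
  as.numeric(fit$residuals)
}

#' Welch power spectral density estimate
#'
#' Averaged modified periodograms: Hann-tapered segments of `seg_s` seconds
#' with fractional `overlap`, one-sided density scaling so that integrating
#' the PSD over frequency recovers the signal's mean power.
#'
#' @param x Numeric vector (one channel, one analysis window).
#' @param fs Sampling rate in Hz.
#' @param seg_s Sub-segment length in seconds (default 2, giving 0.5 Hz
#'   resolution).
#' @param overlap Fractional overlap between segments (default 0.5).
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, seg_s = 2, overlap = 0.5) {
  nseg <- round(seg_s * fs)
  if (length(x) < nseg) {
    stop("welch: signal shorter than one segment", call. = FALSE)
  }
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, length(x) - nseg + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nseg - 1L)) / nseg)) # periodic Hann
  u <- sum(w^2)
  acc <- numeric(nseg)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1L)] * w
    acc <- acc + Mod(stats::fft(seg))^2
  }
  p <- acc / length(starts)
  nhalf <- floor(nseg / 2) + 1L
  psd <- p[seq_len(nhalf)] / (fs * u)
  # one-sided: double everything except DC (and Nyquist when nseg is even)
  dbl <- rep(2, nhalf)
  dbl[1L] <- 1
  if (nseg %% 2 == 0) dbl[nhalf] <- 1
  list(freq = (seq_len(nhalf) - 1L) * fs / nseg, psd = psd * dbl)
}

# Internal: trapezoidal integral of psd over [low, high], interpolating the
# band edges onto the frequency grid.
integrate_band <- function(freq, psd, low_hz, high_hz) {
  if (low_hz < min(freq) || high_hz > max(freq)) {
    stop("band integration: band outside the PSD frequency range", call. = FALSE)
  }
  inside <- freq > low_hz & freq < high_hz
  ff <- c(low_hz, freq[inside], high_hz)
  pp <- stats::approx(freq, psd, xout = ff)$y
  sum(diff(ff) * (pp[-length(pp)] + pp[-1L]) / 2)
}

#' Band power of a single-channel window
#'
#' Linear detrend, Welch PSD, then trapezoidal integration of the density
#' over the band. Non-negative by construction.
#'
#' @param x Numeric vector: one channel's samples for one analysis window.
#'   Must span at least two seconds (the Welch segment length).
#' @param fs Sampling rate in Hz.
#' @param band A `band_definition`, or numeric `c(low_hz, high_hz)`.
#' @param seg_s,overlap Welch estimator parameters (see [welch_psd()]).
#' @return Band power in microvolt-squared.
#' @export
band_power <- function(x, fs, band, seg_s = 2, overlap = 0.5) {
  if (inherits(band, "band_definition")) {
    band <- c(band$low_hz, band$high_hz)
  }
  if (length(x) < 2 * fs) {
    stop("band power: window must span at least 2 s of samples", call. = FALSE)
  }
  spec <- welch_psd(detrend_linear(x), fs, seg_s = seg_s, overlap = overlap)
  integrate_band(spec$freq, spec$psd, band[1L], band[2L])
}

#' EEG workload index for one window
#'
#' Ratio of average frontal/central theta power to average occipital alpha
#' power: `mean(theta_F4, theta_C4) / mean(alpha_O1, alpha_O2)`. A zero or
#' non-finite denominator yields `NA`, which downstream outlier replacement
#' treats like a detected outlier.
#'
#' @param theta_powers Numeric vector of theta-band powers (F4 and C4).
#' @param alpha_powers Numeric vector of alpha-band powers (O1 and O2).
#' @return The index value, or `NA_real_` if undefined.
#' @export
eeg_index_window <- function(theta_powers, alpha_powers) {
  th <- mean(theta_powers)
  al <- mean(alpha_powers)
  if (!is.finite(th) || !is.finite(al) || al <= 0) return(NA_real_)
  val <- th / al
  if (!is.finite(val)) return(NA_real_)
  val
}

#' Replace outliers beyond k standard deviations from the mean
#'
#' Single pass: mean and standard deviation are computed once over the whole
#' series (flagged/`NA` points excluded), elements strictly beyond
#' `mean +/- k_sd * SD` are replaced by the mean of the non-outlier elements.
#' Already-invalid (`NA`/flagged) points are replaced the same way. Points at
#' exactly `k_sd` standard deviations are retained.
#'
#' @param series An `index_series`.
#' @param k_sd Threshold in standard deviations (default 3).
#' @return An `index_series` with outliers replaced; replaced points stay
#'   flagged, and the number of replacements is stored in attribute
#'   `n_replaced`.
#' @export
reject_outliers <- function(series, k_sd = 3) {
  stopifnot(inherits(series, "index_series"))
  if (length(series$t_s) == 0L) {
    stop("outlier rejection: series is empty", call. = FALSE)
  }
  v <- series$value
  usable <- !series$flagged & is.finite(v)
  if (!any(usable)) {
    stop("outlier rejection: no valid values in series", call. = FALSE)
  }
  m <- mean(v[usable])
  s <- stats::sd(v[usable])
  if (!is.finite(s)) s <- 0
  out <- usable & s > 0 & abs(v - m) > k_sd * s
  keep <- usable & !out
  if (!any(keep)) {
    stop("outlier rejection: every value flagged as an outlier", call. = FALSE)
  }
  repl <- mean(v[keep])
  replaced <- out | !usable
  v[replaced] <- repl
  res <- index_series(series$t_s, v, series$step_s, series$label,
                      flagged = replaced, resample = series$resample)
  attr(res, "n_replaced") <- sum(replaced)
  res
}

#' Moving-average smoothing of an index series
#'
#' Zero-phase (centred) moving average of `window_s` seconds; windows shrink
#' at the series edges so length is preserved. With the default 5-s grid and
#' 60-s window this is a 12-point average.
#'
#' @param series An `index_series`.
#' @param window_s Smoothing window in seconds (default 60). Must be at least
#'   one grid step.
#' @return The smoothed `index_series` (flags preserved).
#' @export
smooth_index <- function(series, window_s = 60) {
  stopifnot(inherits(series, "index_series"))
  if (window_s < series$step_s) {
    stop("smoothing: window_s must be at least the grid step", call. = FALSE)
  }
  n <- length(series$value)
  if (n == 0L) return(series)
  k <- max(1L, round(window_s / series$step_s))
  left <- (k - 1L) %/% 2L
  right <- k - 1L - left
  idx <- seq_len(n)
  lo <- pmax(idx - left, 1L)
  hi <- pmin(idx + right, n)
  cs <- cumsum(c(0, series$value))
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  index_series(series$t_s, sm, series$step_s, series$label,
               flagged = series$flagged, resample = series$resample)
}

#' Full EEG workload index pipeline
#'
#' Composition of the whole per-channel chain: zero-phase 0.5-30 Hz bandpass,
#' segmentation into non-overlapping 5-s windows, linear detrend + Welch PSD +
#' band integration per window, theta/alpha index per window, 3-SD outlier
#' replacement, and moving-average smoothing. Only the four channels entering
#' the index (F4, C4, O1, O2) are processed.
#'
#' @param rec An `eeg_recording` containing at least channels F4, C4, O1, O2.
#' @param win_s Analysis window in seconds (default 5).
#' @param bands Named list with `theta` and `alpha` [band_definition()]s.
#' @param bp_low_hz,bp_high_hz Bandpass edges in Hz (defaults 0.5 and 30).
#' @param k_sd Outlier threshold in standard deviations (default 3).
#' @param smooth_s Smoothing window in seconds (default 60); `0` disables
#'   smoothing.
#' @return An `index_series` labelled `"eeg_index"` on the `win_s` grid, with
#'   attribute `n_replaced` (outliers + invalid windows replaced).
#' @export
compute_eeg_index_series <- function(rec, win_s = 5, bands = default_bands(),
                                     bp_low_hz = 0.5, bp_high_hz = 30,
                                     k_sd = 3, smooth_s = 60) {
  stopifnot(inherits(rec, "eeg_recording"))
  theta_ch <- c("F4", "C4")
  alpha_ch <- c("O1", "O2")
  rec <- subset_channels(rec, c(theta_ch, alpha_ch))
  rec <- bandpass_filter(rec, bp_low_hz, bp_high_hz)
  wins <- segment_windows(rec, win_s)
  if (length(wins) == 0L) {
    stop("eeg index: recording shorter than one analysis window", call. = FALSE)
  }
  t_start <- attr(wins, "t_start_s")
  vals <- vapply(wins, function(w) {
    th <- vapply(theta_ch, function(ch) band_power(w[, ch], rec$fs, bands$theta),
                 numeric(1))
    al <- vapply(alpha_ch, function(ch) band_power(w[, ch], rec$fs, bands$alpha),
                 numeric(1))
    eeg_index_window(th, al)
  }, numeric(1))
  series <- index_series(t_start, vals, win_s, "eeg_index", resample = "grid")
  series <- reject_outliers(series, k_sd)
  n_repl <- attr(series, "n_replaced")
  if (smooth_s > 0) series <- smooth_index(series, smooth_s)
  attr(series, "n_replaced") <- n_repl
  series
}
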