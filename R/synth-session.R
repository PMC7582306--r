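#' Default synthetic click generator settings
#'
#' Controller inputs are an inhomogeneous Poisson process with rate
#' `base_hz + gain_hz * workload` (piecewise constant over the workload
#' grid). Left clicks dominate (command + panning inputs).
#'
#' @return Named list of generator parameters.
#' @export
clicks_defaults <- function() {
  list(base_hz = 0.05, gain_hz = 0.8, p_left = 0.7)
}

#' Default per-phase subjective rating settings
#'
#' Mission-phase means for the 0-10 mental-workload and situational-awareness
#' scales, with Gaussian rater noise clipped to the scale.
#'
#' @return Named list of generator parameters.
#' @export
ratings_defaults <- function() {
  list(mwl_mean = c(2.9, 5.9, 7.8), sa_mean = c(9.6, 6.2, 4.0), sd = 1.1)
}

#' Generate a synthetic controller-input log
#'
#' Pure function of `(profile, cfg, seed)`: an inhomogeneous Poisson click
#' process whose rate follows the workload profile.
#'
#' @param profile A `workload_profile`.
#' @param cfg Generator settings; entries override [clicks_defaults()].
#' @param seed Integer random seed.
#' @return A `click_log` data frame with columns `t_s`, `button`.
#' @export
generate_clicks <- function(profile, cfg = list(), seed = 1L) {
  stopifnot(inherits(profile, "workload_profile"))
  cfg <- utils::modifyList(clicks_defaults(), cfg)
  if (cfg$base_hz < 0 || cfg$gain_hz < 0) {
    stop("clicks config: rates must be non-negative", call. = FALSE)
  }
  set.seed(as.integer(seed))
  step <- profile$step_s
  rate <- cfg$base_hz + cfg$gain_hz * profile$level
  times <- numeric(0)
  for (i in seq_along(profile$grid_s)) {
    k <- stats::rpois(1, rate[i] * step)
    if (k > 0) {
      times <- c(times, profile$grid_s[i] + stats::runif(k) * step)
    }
  }
  times <- sort(times)
  button <- if (length(times)) {
    ifelse(stats::runif(length(times)) < cfg$p_left, "left", "right")
  } else {
    character(0)
  }
  out <- data.frame(t_s = times, button = button, stringsAsFactors = FALSE)
  class(out) <- c("click_log", "data.frame")
  out
}

#' Generate per-phase subjective ratings
#'
#' @param cfg Settings; entries override [ratings_defaults()].
#' @param seed Integer random seed.
#' @return Data frame with columns `phase`, `mwl`, `sa` (0-10 scales).
#' @export
generate_ratings <- function(cfg = list(), seed = 1L) {
  cfg <- utils::modifyList(ratings_defaults(), cfg)
  set.seed(as.integer(seed))
  ph <- mission_phases()
  mwl <- pmin(10, pmax(0, stats::rnorm(length(ph), cfg$mwl_mean, cfg$sd)))
  sa <- pmin(10, pmax(0, stats::rnorm(length(ph), cfg$sa_mean, cfg$sd)))
  data.frame(phase = ph, mwl = mwl, sa = sa, stringsAsFactors = FALSE)
}

#' Full synthetic-session configuration
#'
#' Bundles the schedule, the latent workload levels and all per-stream
#' generator settings under one master seed. Per-stream settings supplied as
#' partial lists are merged over the stream defaults, so
#' `session_config(eeg = list(fs = 256))` changes only the EEG sampling rate.
#'
#' @param schedule A `phase_schedule` (default: canonical 5/10/10/10/5 min).
#' @param levels Five latent workload levels in `[0, 1]`, one per phase.
#' @param seed Master seed; every stream derives its own sub-seed from it,
#'   so adding a stream never perturbs the others.
#' @param profile_step_s Workload-profile grid step in seconds.
#' @param eeg,gaze,uav,clicks,ratings Partial per-stream settings merged over
#'   [eeg_defaults()], [gaze_defaults()], [uav_defaults()],
#'   [clicks_defaults()] and [ratings_defaults()].
#' @return A `session_config` list.
#' @export
session_config <- function(schedule = make_phase_schedule(),
                           levels = c(0.05, 0.2, 0.55, 0.9, 0.15),
                           seed = 1L, profile_step_s = 5,
                           eeg = list(), gaze = list(), uav = list(),
                           clicks = list(), ratings = list()) {
  cfg <- list(
    schedule = schedule,
    levels = levels,
    seed = as.integer(seed),
    profile_step_s = profile_step_s,
    eeg = utils::modifyList(eeg_defaults(), eeg),
    gaze = utils::modifyList(gaze_defaults(), gaze),
    uav = utils::modifyList(uav_defaults(), uav),
    clicks = utils::modifyList(clicks_defaults(), clicks),
    ratings = utils::modifyList(ratings_defaults(), ratings)
  )
  class(cfg) <- "session_config"
  validate_session_config(cfg)
  cfg
}

# Internal: fail with a message naming the offending configuration key.
validate_session_config <- function(cfg) {
  if (!inherits(cfg$schedule, "phase_schedule")) {
    stop("config error in `schedule`: not a valid phase schedule", call. = FALSE)
  }
  if (!is.numeric(cfg$levels) || length(cfg$levels) != nrow(cfg$schedule) ||
      any(cfg$levels < 0 | cfg$levels > 1)) {
    stop("config error in `levels`: need one workload level in [0, 1] per phase",
         call. = FALSE)
  }
  if (cfg$eeg$fs < 64) {
    stop("config error in `eeg.fs`: sampling rate must be at least 64 Hz",
         call. = FALSE)
  }
  if (cfg$gaze$fs < 10) {
    stop("config error in `gaze.fs`: sampling rate must be at least 10 Hz",
         call. = FALSE)
  }
  if (any(cfg$uav$counts < 0)) {
    stop("config error in `uav.counts`: fleet sizes must be non-negative",
         call. = FALSE)
  }
  if (cfg$clicks$base_hz < 0 || cfg$clicks$gain_hz < 0) {
    stop("config error in `clicks`: rates must be non-negative", call. = FALSE)
  }
  invisible(cfg)
}

#' Derive a per-stream sub-seed from the master seed
#'
#' Linear-congruential mix keeping the result inside the 32-bit integer
#' range; each stream name maps to a distinct, reproducible sub-seed.
#'
#' @param seed Master integer seed.
#' @param stream One of `"eeg"`, `"gaze"`, `"uav"`, `"clicks"`, `"ratings"`,
#'   `"study"`.
#' @return An integer sub-seed.
#' @export
derive_seed <- function(seed, stream) {
  streams <- c("eeg", "gaze", "uav", "clicks", "ratings", "study")
  k <- match(stream, streams)
  if (is.na(k)) stop("unknown stream name: ", stream, call. = FALSE)
  as.integer((abs(as.numeric(seed)) * 48271 + k * 96731) %% 2147483647)
}

#' Simulate one complete synthetic session
#'
#' Generates every data stream of one participant session from a single
#' configuration and master seed: EEG, gaze, UAV flight logs, controller
#' clicks and subjective ratings, together with the latent workload profile
#' that drives them (the ground truth for recovery tests). Fully
#' deterministic given `(config)`.
#'
#' @param config A [session_config()].
#' @return A `session_bundle` list with elements `schedule`, `truth`
#'   (workload profile), `eeg`, `gaze`, `uav_logs`, `clicks`, `ratings`,
#'   `config`.
#' @examples
#' \donttest{
#' cfg <- session_config(schedule = make_phase_schedule(c(30, 60, 60, 60, 30)),
#'                       seed = 7)
#' bundle <- simulate_session(cfg)
#' bundle$ratings
#' }
#' @export
simulate_session <- function(config = session_config()) {
  validate_session_config(config)
  profile <- generate_workload_profile(config$schedule, config$levels,
                                       config$profile_step_s)
  bundle <- list(
    schedule = config$schedule,
    truth = profile,
    eeg = generate_eeg(profile, config$eeg, derive_seed(config$seed, "eeg")),
    gaze = generate_gaze(profile, config$gaze, derive_seed(config$seed, "gaze")),
    uav_logs = generate_uav_logs(config$schedule, config$uav,
                                 derive_seed(config$seed, "uav"), profile),
    clicks = generate_clicks(profile, config$clicks,
                             derive_seed(config$seed, "clicks")),
    ratings = generate_ratings(config$ratings,
                               derive_seed(config$seed, "ratings")),
    config = config
  )
  class(bundle) <- "session_bundle"
  bundle
}

#' @export
print.session_bundle <- function(x, ...) {
  span <- schedule_span(x$schedule)
  cat(sprintf("session_bundle: %g s session, seed %d\n",
              span[2L] - span[1L], x$config$seed))
  cat(sprintf("  eeg: %d ch @ %g Hz | gaze: %d samples | uav logs: %d records | clicks: %d\n",
              ncol(x$eeg$data), x$eeg$fs, nrow(x$gaze), nrow(x$uav_logs),
              nrow(x$clicks)))
  invisible(x)
}
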