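#' Default synthetic UAV flight-log generator settings
#'
#' UAVs are released in cohorts at the start of each mission phase so that
#' `counts[p]` vehicles are active in phase p (default 3/6/9) and remain
#' active until the mission ends. Each penalty category degrades through a
#' marked Poisson process: events arrive at
#' `base rate + rate_gain * workload` per UAV-minute, push the category into
#' the +0.5 or +1 penalty band, and recover after an exponential episode
#' duration. Newly released UAVs start outside a team and with sensors off
#' until the (exponential) operator assignment delays elapse, reproducing the
#' task-index spikes seen at phase starts.
#'
#' @return Named list of generator parameters.
#' @export
uav_defaults <- function() {
  list(
    counts = c(3, 6, 9),
    log_step_s = 5,
    nav_rate_per_min = 0.24, comm_rate_per_min = 0.24,
    fuel_rate_per_min = 0.12, hold_rate_per_min = 0.12,
    rate_gain_per_min = 0.7,
    recover_mean_s = 25,
    assign_delay_mean_s = 30, sensor_delay_mean_s = 20,
    p_severe = 0.4,
    nominal = list(nav_acc_m = 8, comm_pct = 85, fuel_ratio = 3,
                   fuel_needed = 100),
    degraded = list(nav_acc_m = c(15, 30), comm_pct = c(60, 40),
                    fuel_ratio = c(1.7, 1.0))
  )
}

# Internal: draw event times of an inhomogeneous Poisson process whose rate
# (events per minute) is constant within each schedule phase.
phase_poisson_times <- function(schedule, active_from, active_to,
                                rate_per_min_by_phase) {
  times <- numeric(0)
  for (p in seq_len(nrow(schedule))) {
    lo <- max(schedule$start_s[p], active_from)
    hi <- min(schedule$end_s[p], active_to)
    if (hi <= lo) next
    lam <- rate_per_min_by_phase[p] * (hi - lo) / 60
    k <- stats::rpois(1, lam)
    if (k > 0) times <- c(times, stats::runif(k, lo, hi))
  }
  sort(times)
}

# Internal: severity level (0 nominal / 1 moderate / 2 severe) at query
# times, given episode onsets, durations and severities; overlapping
# episodes take the maximum severity.
episode_level_at <- function(t_query, onsets, durations, severities) {
  lev <- integer(length(t_query))
  for (e in seq_along(onsets)) {
    cover <- t_query >= onsets[e] & t_query < onsets[e] + durations[e]
    lev[cover] <- pmax(lev[cover], severities[e])
  }
  lev
}

#' Generate synthetic UAV flight logs
#'
#' Pure function of `(schedule, cfg, seed[, profile])`. Produces per-UAV
#' state records on a regular `log_step_s` grid spanning each UAV's active
#' interval (release at its cohort's phase start until mission end). With a
#' `NULL` profile, event rates are the workload-independent base rates.
#'
#' @param schedule A `phase_schedule`.
#' @param cfg Generator settings; entries override [uav_defaults()].
#' @param seed Integer random seed.
#' @param profile Optional `workload_profile` modulating the event rates.
#' @return A `uav_log_set` data frame with columns `t_s`, `uav_id`,
#'   `nav_acc_m`, `comm_pct`, `fuel_onboard`, `fuel_needed`,
#'   `autopilot_hold`, `in_team`, `sensors_active`.
#' @export
generate_uav_logs <- function(schedule, cfg = list(), seed = 1L,
                              profile = NULL) {
  stopifnot(inherits(schedule, "phase_schedule"))
  cfg <- utils::modifyList(uav_defaults(), cfg)
  counts <- cfg$counts
  if (length(counts) != length(mission_phases()) || any(counts < 0)) {
    stop("uav config: counts must give one non-negative fleet size per mission phase",
         call. = FALSE)
  }
  if (any(diff(counts) < 0)) {
    stop("uav config: per-phase UAV counts must be non-decreasing", call. = FALSE)
  }
  set.seed(as.integer(seed))
  mrows <- match(mission_phases(), schedule$phase)
  release_t <- schedule$start_s[mrows]
  mission_end <- schedule$end_s[mrows[length(mrows)]]
  cohort_sizes <- diff(c(0, counts))

  # per-phase event rates (events per UAV-minute)
  lev <- if (is.null(profile)) rep(0, nrow(schedule)) else {
    workload_at(profile, schedule$start_s + 1e-9)
  }
  rate_for <- function(base) base + cfg$rate_gain_per_min * lev

  all_logs <- list()
  uid <- 0L
  for (cohort in seq_along(cohort_sizes)) {
    for (k in seq_len(cohort_sizes[cohort])) {
      uid <- uid + 1L
      rel <- release_t[cohort]
      tgrid <- seq(rel, mission_end, by = cfg$log_step_s)

      sim_category <- function(base_rate) {
        ev <- phase_poisson_times(schedule, rel, mission_end, rate_for(base_rate))
        if (length(ev) == 0L) {
          return(integer(length(tgrid)))
        }
        dur <- stats::rexp(length(ev), 1 / cfg$recover_mean_s)
        sev <- 1L + stats::rbinom(length(ev), 1L, cfg$p_severe)
        episode_level_at(tgrid, ev, dur, sev)
      }
      nav_lev <- sim_category(cfg$nav_rate_per_min)
      comm_lev <- sim_category(cfg$comm_rate_per_min)
      fuel_lev <- sim_category(cfg$fuel_rate_per_min)
      hold_lev <- sim_category(cfg$hold_rate_per_min)
      assign_delay <- if (cfg$assign_delay_mean_s > 0) {
        stats::rexp(1, 1 / cfg$assign_delay_mean_s)
      } else 0
      sensor_delay <- if (cfg$sensor_delay_mean_s > 0) {
        stats::rexp(1, 1 / cfg$sensor_delay_mean_s)
      } else 0

      nav <- c(cfg$nominal$nav_acc_m, cfg$degraded$nav_acc_m)[nav_lev + 1L]
      comm <- c(cfg$nominal$comm_pct, cfg$degraded$comm_pct)[comm_lev + 1L]
      ratio <- c(cfg$nominal$fuel_ratio, cfg$degraded$fuel_ratio)[fuel_lev + 1L]
      all_logs[[uid]] <- data.frame(
        t_s = tgrid,
        uav_id = sprintf("UAV%02d", uid),
        nav_acc_m = nav,
        comm_pct = comm,
        fuel_onboard = ratio * cfg$nominal$fuel_needed,
        fuel_needed = cfg$nominal$fuel_needed,
        autopilot_hold = hold_lev > 0L,
        in_team = tgrid >= rel + assign_delay,
        sensors_active = tgrid >= rel + sensor_delay,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(all_logs) == 0L) {
    out <- data.frame(t_s = numeric(0), uav_id = character(0),
                      nav_acc_m = numeric(0), comm_pct = numeric(0),
                      fuel_onboard = numeric(0), fuel_needed = numeric(0),
                      autopilot_hold = logical(0), in_team = logical(0),
                      sensors_active = logical(0), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, all_logs)
    out <- out[order(out$t_s, out$uav_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("uav_log_set", "data.frame")
  out
}
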