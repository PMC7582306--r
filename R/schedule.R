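#' Build the five-phase session schedule
#'
#' A supervision session consists of a pre-mission rest, three back-to-back
#' mission phases of increasing difficulty, and a post-mission rest. The
#' schedule is contiguous and starts at t = 0 s; every interval is half-open
#' `[start_s, end_s)`.
#'
#' @param durations_s Numeric vector of exactly five phase durations in
#'   seconds, in session order (`PreRest`, `Phase1`, `Phase2`, `Phase3`,
#'   `PostRest`). Defaults to the canonical 5/10/10/10/5-minute layout.
#' @return A `phase_schedule` data frame with columns `phase`, `start_s`,
#'   `end_s`.
#' @examples
#' sched <- make_phase_schedule()
#' schedule_span(sched) # 0 .. 2400 s
#' @export
make_phase_schedule <- function(durations_s = c(300, 600, 600, 600, 300)) {
  if (!is.numeric(durations_s) || length(durations_s) != 5L) {
    stop("schedule: exactly five phase durations are required", call. = FALSE)
  }
  if (any(!is.finite(durations_s)) || any(durations_s <= 0)) {
    stop("schedule: phase durations must be positive and finite", call. = FALSE)
  }
  ends <- cumsum(as.numeric(durations_s))
  sched <- data.frame(
    phase = phase_labels(),
    start_s = c(0, ends[-5L]),
    end_s = ends,
    stringsAsFactors = FALSE
  )
  class(sched) <- c("phase_schedule", "data.frame")
  sched
}

#' Canonical phase labels, in session order
#' @return Character vector of the five phase labels.
#' @export
phase_labels <- function() {
  c("PreRest", "Phase1", "Phase2", "Phase3", "PostRest")
}

#' The three mission phases (rest phases excluded)
#' @return Character vector `c("Phase1", "Phase2", "Phase3")`.
#' @export
mission_phases <- function() {
  c("Phase1", "Phase2", "Phase3")
}

#' Session time span covered by a schedule
#' @param schedule A `phase_schedule`.
#' @return Numeric `c(start_s, end_s)` of the whole session.
#' @export
schedule_span <- function(schedule) {
  stopifnot(inherits(schedule, "phase_schedule"))
  c(schedule$start_s[1L], schedule$end_s[nrow(schedule)])
}

#' Phase membership of time stamps
#'
#' Each phase owns the half-open interval `[start_s, end_s)`; times outside
#' the session span map to `NA`.
#'
#' @param schedule A `phase_schedule`.
#' @param t_s Numeric vector of times (seconds from session start).
#' @return Character vector of phase labels (`NA` outside the span).
#' @export
phase_at <- function(schedule, t_s) {
  stopifnot(inherits(schedule, "phase_schedule"))
  breaks <- c(schedule$start_s, schedule$end_s[nrow(schedule)])
  idx <- findInterval(t_s, breaks)
  out <- rep(NA_character_, length(t_s))
  ok <- !is.na(idx) & idx >= 1L & idx <= nrow(schedule)
  out[ok] <- schedule$phase[idx[ok]]
  out
}

#' Latent workload profile over a session
#'
#' The latent workload driver is piecewise constant per phase: one level in
#' `[0, 1]` per schedule phase, sampled on a uniform grid of cell-start time
#' stamps. It is the ground truth that the synthetic stream generators encode
#' and that recovery tests measure against.
#'
#' @param schedule A `phase_schedule`.
#' @param levels Numeric vector of five workload levels in `[0, 1]`, one per
#'   phase. The default rises across the mission phases and returns only
#'   partially to baseline after the mission.
#' @param grid_step_s Grid step in seconds (default 5).
#' @return A `workload_profile`: list with `grid_s`, `level`, `step_s`.
#' @export
generate_workload_profile <- function(schedule,
                                      levels = c(0.05, 0.2, 0.55, 0.9, 0.15),
                                      grid_step_s = 5) {
  stopifnot(inherits(schedule, "phase_schedule"))
  if (!is.numeric(levels) || length(levels) != nrow(schedule)) {
    stop("workload profile: one level per schedule phase is required", call. = FALSE)
  }
  if (any(!is.finite(levels)) || any(levels < 0) || any(levels > 1)) {
    stop("workload profile: levels must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(grid_step_s) || length(grid_step_s) != 1L || grid_step_s <= 0) {
    stop("workload profile: grid_step_s must be a positive scalar", call. = FALSE)
  }
  span <- schedule_span(schedule)
  n <- floor((span[2L] - span[1L]) / grid_step_s)
  grid <- span[1L] + (seq_len(n) - 1L) * grid_step_s
  lev <- levels[match(phase_at(schedule, grid), schedule$phase)]
  structure(
    list(grid_s = grid, level = lev, step_s = grid_step_s, schedule = schedule),
    class = "workload_profile"
  )
}

#' Evaluate a workload profile at arbitrary times
#'
#' Piecewise-constant (last grid value carried forward) lookup; times before
#' the first grid stamp take the first level.
#'
#' @param profile A `workload_profile`.
#' @param t_s Numeric vector of times in seconds.
#' @return Numeric workload levels in `[0, 1]`.
#' @export
workload_at <- function(profile, t_s) {
  stopifnot(inherits(profile, "workload_profile"))
  idx <- findInterval(t_s, profile$grid_s)
  idx[idx < 1L] <- 1L
  profile$level[idx]
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat("Session schedule (", nrow(x), " phases, ",
      x$end_s[nrow(x)] - x$start_s[1L], " s total)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
print.workload_profile <- function(x, ...) {
  cat("Latent workload profile: ", length(x$grid_s), " grid points, step ",
      x$step_s, " s, levels in [", min(x$level), ", ", max(x$level), "]\n",
      sep = "")
  invisible(x)
}
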