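#' Default secondary-task penalty table
#'
#' Thresholds and weights for the six pending-task categories scored from a
#' UAV flight-log record. Categories and penalties:
#' \itemize{
#'   \item navigation accuracy: above 25 m +1, 10-25 m +0.5, below 10 m +0
#'   \item comm strength: below 50\% +1, 50-70\% +0.5, above 70\% +0
#'   \item fuel margin `r = fuel_onboard / fuel_needed`: `r < 1.5` +1,
#'     `1.5 <= r < 2` +0.5, `r >= 2` +0
#'   \item autopilot in hold +1
#'   \item not assigned to a team +1
#'   \item no sensors active +1
#' }
#' Band edges are lower-inclusive: nav of exactly 10 or 25 m and comm of
#' exactly 50 or 70\% score the middle (+0.5) band. Per-UAV maximum is 6.
#'
#' @return A `penalty_table` list of thresholds.
#' @export
penalty_table <- function() {
  structure(
    list(
      nav_poor_m = 25, nav_adequate_m = 10,
      comm_poor_pct = 50, comm_adequate_pct = 70,
      fuel_critical_ratio = 1.5, fuel_low_ratio = 2,
      max_per_uav = 6
    ),
    class = "penalty_table"
  )
}

#' Secondary-task penalty score of UAV flight-log records
#'
#' Weighted count of pending system-maintenance tasks for one or more
#' records: the sum of the six category penalties of [penalty_table()].
#' Every record scores between 0 (all nominal) and 6 (everything pending).
#' A `fuel_needed` of zero is treated as an infinite (adequate) margin.
#'
#' @param records Data frame (or single-record list) with fields `nav_acc_m`,
#'   `comm_pct`, `fuel_onboard`, `fuel_needed`, `autopilot_hold`, `in_team`,
#'   `sensors_active`.
#' @param table A `penalty_table`.
#' @return Numeric vector of penalty scores, one per record.
#' @export
uav_penalty <- function(records, table = penalty_table()) {
  records <- as.data.frame(records)
  req <- c("nav_acc_m", "comm_pct", "fuel_onboard", "fuel_needed",
           "autopilot_hold", "in_team", "sensors_active")
  miss <- setdiff(req, names(records))
  if (length(miss)) {
    stop("task index: record is missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (any(records$nav_acc_m < 0, na.rm = TRUE) ||
      any(records$comm_pct < 0 | records$comm_pct > 100, na.rm = TRUE) ||
      any(records$fuel_onboard < 0 | records$fuel_needed < 0, na.rm = TRUE)) {
    stop("task index: record fields outside their valid ranges", call. = FALSE)
  }
  nav <- ifelse(records$nav_acc_m > table$nav_poor_m, 1,
                ifelse(records$nav_acc_m >= table$nav_adequate_m, 0.5, 0))
  comm <- ifelse(records$comm_pct < table$comm_poor_pct, 1,
                 ifelse(records$comm_pct <= table$comm_adequate_pct, 0.5, 0))
  ratio <- ifelse(records$fuel_needed <= 0, Inf,
                  records$fuel_onboard / records$fuel_needed)
  fuel <- ifelse(ratio < table$fuel_critical_ratio, 1,
                 ifelse(ratio < table$fuel_low_ratio, 0.5, 0))
  hold <- ifelse(as.logical(records$autopilot_hold) %in% TRUE, 1, 0)
  team <- ifelse(as.logical(records$in_team) %in% TRUE, 0, 1)
  sens <- ifelse(as.logical(records$sensors_active) %in% TRUE, 0, 1)
  nav + comm + fuel + hold + team + sens
}

#' Secondary-task index time series
#'
#' At each grid time the fleet-level task index is the sum over UAVs of the
#' penalty of that UAV's latest record at or before the grid time (last
#' observation carried forward). A UAV contributes 0 before its first record
#' (i.e. before it is released). The cap of 6 points is per UAV, so the
#' series can exceed 6 with several UAVs released.
#'
#' @param logs UAV log data frame with columns `t_s`, `uav_id` and the
#'   penalty fields of [uav_penalty()].
#' @param table A `penalty_table`.
#' @param step_s Grid step in seconds (default 5).
#' @param t_range Optional numeric `c(start_s, end_s)` for the output grid;
#'   defaults to the span of the logs.
#' @return An `index_series` labelled `"task_index"` with `resample = "locf"`.
#' @export
task_index_series <- function(logs, table = penalty_table(), step_s = 5,
                              t_range = NULL) {
  logs <- as.data.frame(logs)
  if (nrow(logs) == 0L) {
    stop("task index: no log records", call. = FALSE)
  }
  if (is.null(t_range)) t_range <- range(logs$t_s)
  n <- max(1L, floor((t_range[2L] - t_range[1L]) / step_s))
  grid <- t_range[1L] + (seq_len(n) - 1L) * step_s
  pen <- uav_penalty(logs, table)
  total <- numeric(length(grid))
  for (u in unique(logs$uav_id)) {
    sel <- logs$uav_id == u
    tt <- logs$t_s[sel]
    pp <- pen[sel]
    ord <- order(tt)
    tt <- tt[ord]
    pp <- pp[ord]
    idx <- findInterval(grid, tt)
    total <- total + c(0, pp)[idx + 1L]
  }
  index_series(grid, total, step_s, "task_index", resample = "locf")
}

#' Controller-input counts in fixed bins
#'
#' Total clicks (both buttons) in half-open bins `[t, t + bin_s)`. The
#' default 2-minute bin follows standard controller-input workload counting.
#'
#' @param clicks Click log data frame with column `t_s` (and optionally
#'   `button`).
#' @param bin_s Bin width in seconds (default 120).
#' @param t_range Optional numeric `c(start_s, end_s)` for the binning grid;
#'   defaults to `[0, max click time]` rounded up to a whole bin.
#' @return An `index_series` labelled `"control_input"` with
#'   `resample = "locf"`; `t_s` holds the bin start times.
#' @export
click_count_series <- function(clicks, bin_s = 120, t_range = NULL) {
  clicks <- as.data.frame(clicks)
  if (is.null(t_range)) {
    hi <- if (nrow(clicks)) max(clicks$t_s) else bin_s
    t_range <- c(0, ceiling(hi / bin_s) * bin_s)
  }
  n_bins <- max(1L, floor((t_range[2L] - t_range[1L]) / bin_s))
  starts <- t_range[1L] + (seq_len(n_bins) - 1L) * bin_s
  counts <- integer(n_bins)
  if (nrow(clicks)) {
    b <- floor((clicks$t_s - t_range[1L]) / bin_s) + 1
    b <- b[b >= 1 & b <= n_bins]
    if (length(b)) counts <- tabulate(b, n_bins)
  }
  index_series(starts, counts, bin_s, "control_input", resample = "locf")
}
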