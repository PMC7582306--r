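#' Uniformly gridded scalar index series
#'
#' The common container for every derived workload measure: the EEG index,
#' windowed visual entropy, the secondary-task index, binned click counts and
#' fused measures. Values sit on a uniform time grid of `step_s` seconds;
#' `t_s` holds the start stamp of each grid cell (half-open `[t, t + step_s)`).
#' Individual points can be flagged invalid (e.g. entropy windows with too few
#' transitions); flagged points are excluded from normalization and dropped
#' pairwise before correlation.
#'
#' @param t_s Numeric vector of grid-cell start times (seconds).
#' @param value Numeric vector of the same length.
#' @param step_s Grid step in seconds.
#' @param label Short measure label (e.g. `"eeg_index"`).
#' @param flagged Logical vector marking invalid points (default all `FALSE`;
#'   `NA` values are flagged automatically).
#' @param resample Resampling convention used when aligning with other series:
#'   `"grid"` for natively gridded measures, `"locf"` for step-valued measures
#'   (task index, click bins) that carry the last observation forward.
#' @return An `index_series` object.
#' @export
index_series <- function(t_s, value, step_s, label = "",
                         flagged = NULL, resample = c("grid", "locf")) {
  resample <- match.arg(resample)
  t_s <- as.numeric(t_s)
  value <- as.numeric(value)
  if (length(t_s) != length(value)) {
    stop("index series: t_s and value must have equal length", call. = FALSE)
  }
  if (length(t_s) > 1L && any(diff(t_s) <= 0)) {
    stop("index series: time stamps must be strictly increasing", call. = FALSE)
  }
  if (!is.numeric(step_s) || length(step_s) != 1L || step_s <= 0) {
    stop("index series: step_s must be a positive scalar", call. = FALSE)
  }
  if (is.null(flagged)) flagged <- rep(FALSE, length(value))
  flagged <- as.logical(flagged) | is.na(value)
  structure(
    list(t_s = t_s, value = value, step_s = as.numeric(step_s),
         label = as.character(label), flagged = flagged, resample = resample),
    class = "index_series"
  )
}

#' @export
print.index_series <- function(x, ...) {
  ok <- !x$flagged
  cat(sprintf(
    "index_series '%s': %d points, step %g s, span [%g, %g] s, %d flagged\n",
    x$label, length(x$t_s), x$step_s,
    if (length(x$t_s)) min(x$t_s) else NA, if (length(x$t_s)) max(x$t_s) else NA,
    sum(x$flagged)))
  if (any(ok)) {
    cat(sprintf("  valid values: mean %.4g, range [%.4g, %.4g]\n",
                mean(x$value[ok]), min(x$value[ok]), max(x$value[ok])))
  }
  invisible(x)
}

#' @export
as.data.frame.index_series <- function(x, ...) {
  data.frame(t_s = x$t_s, value = x$value, flagged = x$flagged)
}

#' @export
length.index_series <- function(x) length(x$t_s)

# Internal: valid (unflagged, finite) values of a series.
series_valid_values <- function(series) {
  series$value[!series$flagged & is.finite(series$value)]
}

# Internal: mean of valid values inside a half-open time window [from, to).
series_window_mean <- function(series, from, to) {
  sel <- series$t_s >= from & series$t_s < to & !series$flagged &
    is.finite(series$value)
  if (!any(sel)) return(NA_real_)
  mean(series$value[sel])
}
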