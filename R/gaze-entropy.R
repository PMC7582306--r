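#' Screen region-of-interest layout
#'
#' Rectangular regions of interest (ROIs) on the normalized `[0,1]^2` screen.
#' Row order is the priority order used to resolve overlaps; each rectangle is
#' half-open, `[x_min, x_max) x [y_min, y_max)`.
#'
#' @param regions Data frame with columns `id`, `x_min`, `y_min`, `x_max`,
#'   `y_max` (top row = highest priority).
#' @return A validated `roi_layout` data frame.
#' @export
roi_layout <- function(regions) {
  req <- c("id", "x_min", "y_min", "x_max", "y_max")
  if (!is.data.frame(regions) || !all(req %in% names(regions)) ||
      nrow(regions) == 0L) {
    stop("roi layout: need a non-empty data frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(regions$id)) {
    stop("roi layout: region ids must be unique", call. = FALSE)
  }
  if (any(regions$x_max <= regions$x_min) || any(regions$y_max <= regions$y_min)) {
    stop("roi layout: rectangles must be non-degenerate", call. = FALSE)
  }
  regions$id <- as.character(regions$id)
  class(regions) <- c("roi_layout", "data.frame")
  regions
}

#' Default 3 x 3 grid of UAV regions of interest
#'
#' Nine equally sized tiles emulating the per-UAV panels of a one-to-many
#' control interface, inset slightly within each grid cell so the tiles do
#' not touch.
#'
#' @param n_side Tiles per side (default 3).
#' @param inset Margin between a grid cell edge and its tile (default 0.02).
#' @return A `roi_layout` with ids `UAV1` ... `UAVn`.
#' @export
default_roi_layout <- function(n_side = 3, inset = 0.02) {
  cell <- 1 / n_side
  idx <- seq_len(n_side^2)
  col <- (idx - 1L) %% n_side
  row <- (idx - 1L) %/% n_side
  roi_layout(data.frame(
    id = paste0("UAV", idx),
    x_min = col * cell + inset,
    y_min = row * cell + inset,
    x_max = (col + 1L) * cell - inset,
    y_max = (row + 1L) * cell - inset,
    stringsAsFactors = FALSE
  ))
}

# Internal: ROI centre coordinates as a 2-column matrix.
roi_centers <- function(layout) {
  cbind(x = (layout$x_min + layout$x_max) / 2,
        y = (layout$y_min + layout$y_max) / 2)
}

#' Combine binocular gaze samples into one monocular sequence
#'
#' Both eyes valid: midpoint of the two gaze points. One eye valid: that
#' eye's coordinates. Neither valid: the sample is marked invalid and carries
#' `NA` coordinates (excluded from the transition sequence downstream).
#'
#' @param stream A gaze stream data frame with columns `t_s`, `left_x`,
#'   `left_y`, `left_valid`, `right_x`, `right_y`, `right_valid`.
#' @return Data frame with columns `t_s`, `x`, `y`, `valid`.
#' @export
combine_eyes <- function(stream) {
  req <- c("t_s", "left_x", "left_y", "left_valid",
           "right_x", "right_y", "right_valid")
  if (!all(req %in% names(stream))) {
    stop("gaze: stream must contain columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  lv <- as.logical(stream$left_valid) %in% TRUE
  rv <- as.logical(stream$right_valid) %in% TRUE
  x <- ifelse(lv & rv, (stream$left_x + stream$right_x) / 2,
              ifelse(lv, stream$left_x, ifelse(rv, stream$right_x, NA_real_)))
  y <- ifelse(lv & rv, (stream$left_y + stream$right_y) / 2,
              ifelse(lv, stream$left_y, ifelse(rv, stream$right_y, NA_real_)))
  data.frame(t_s = stream$t_s, x = x, y = y, valid = lv | rv)
}

#' Assign gaze samples to regions of interest
#'
#' First region (in layout priority order) whose half-open rectangle contains
#' the point; `NA` if the sample is invalid or lies outside every region.
#'
#' @param samples Data frame with columns `x`, `y` (and optionally `valid`).
#' @param layout A `roi_layout`.
#' @return Character vector of region ids (`NA` where unassigned).
#' @export
assign_roi <- function(samples, layout) {
  layout <- roi_layout(as.data.frame(layout))
  out <- rep(NA_character_, nrow(samples))
  ok <- if ("valid" %in% names(samples)) samples$valid %in% TRUE else TRUE
  ok <- ok & is.finite(samples$x) & is.finite(samples$y)
  for (i in rev(seq_len(nrow(layout)))) {
    # reverse order so earlier (higher-priority) regions overwrite later ones
    hit <- ok &
      samples$x >= layout$x_min[i] & samples$x < layout$x_max[i] &
      samples$y >= layout$y_min[i] & samples$y < layout$y_max[i]
    out[hit] <- layout$id[i]
  }
  out
}

#' Collapse an ROI sample sequence into dwells and transition events
#'
#' Consecutive samples in the same region merge into one dwell, so
#' self-transitions are structurally impossible. Invalid / off-region samples
#' form gaps: a gap of at most `gap_max_s` is bridged (the dwell continues),
#' a longer gap breaks the sequence without emitting a transition across it.
#' Each change of dwell region emits one `(from, to)` event stamped with the
#' onset time of the new dwell.
#'
#' @param t_s Sample time stamps (strictly increasing).
#' @param roi Character vector of region ids (`NA` = invalid/off-region).
#' @param gap_max_s Longest bridgeable gap in seconds (default 1).
#' @return Data frame with columns `t_s`, `from`, `to` (zero rows if fewer
#'   than two dwells survive).
#' @export
collapse_to_transitions <- function(t_s, roi, gap_max_s = 1) {
  keep <- !is.na(roi)
  t <- t_s[keep]
  r <- roi[keep]
  n <- length(t)
  empty <- data.frame(t_s = numeric(0), from = character(0),
                      to = character(0), stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  seg_break <- c(TRUE, diff(t) > gap_max_s)
  seg <- cumsum(seg_break)
  change <- seg_break | c(TRUE, r[-1L] != r[-n])
  dw_t <- t[change]
  dw_r <- r[change]
  dw_seg <- seg[change]
  m <- length(dw_t)
  if (m < 2L) return(empty)
  same_seg <- dw_seg[-1L] == dw_seg[-m]
  data.frame(t_s = dw_t[-1L][same_seg],
             from = dw_r[-m][same_seg],
             to = dw_r[-1L][same_seg],
             stringsAsFactors = FALSE)
}

#' Build an ROI transition count matrix
#'
#' @param events Transition events from [collapse_to_transitions()].
#' @param roi_ids State set (row/column order); defaults to the ids present
#'   in the events.
#' @return Integer matrix `counts[i, j]` = transitions from region i to j;
#'   the diagonal is structurally zero.
#' @export
transition_matrix <- function(events, roi_ids = NULL) {
  if (is.null(roi_ids)) {
    roi_ids <- sort(unique(c(events$from, events$to)))
  }
  roi_ids <- as.character(roi_ids)
  tab <- table(factor(events$from, levels = roi_ids),
               factor(events$to, levels = roi_ids))
  mat <- matrix(as.integer(tab), nrow = length(roi_ids),
                dimnames = list(from = roi_ids, to = roi_ids))
  mat
}

#' Visual entropy of a transition matrix
#'
#' Conditional entropy (bits) of the gaze transition chain, weighted by the
#' empirical prior-state distribution:
#' `H = -sum_i p(X_i) sum_j p(Y_ij | X_i) log2 p(Y_ij | X_i)`,
#' with `p(X_i)` the row sum over the total count and `p(Y_ij | X_i)` the
#' row-normalized counts. Zero-probability cells and empty rows contribute
#' nothing. High H means disordered scanning; a deterministic scan gives 0.
#'
#' @param counts Non-negative count matrix (rows = prior region).
#' @return Entropy in bits (`NA_real_` for an empty matrix).
#' @export
visual_entropy <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) {
    stop("entropy: transition counts must be non-negative", call. = FALSE)
  }
  total <- sum(counts)
  if (total < 1) return(NA_real_)
  rs <- rowSums(counts)
  h <- 0
  for (i in seq_len(nrow(counts))) {
    if (rs[i] == 0) next
    p <- counts[i, ] / rs[i]
    p <- p[p > 0]
    h <- h + (rs[i] / total) * (-sum(p * log2(p)))
  }
  h
}

#' Windowed visual-entropy series from a raw gaze stream
#'
#' Eye combination, ROI assignment and dwell collapsing, followed by a
#' sliding-window entropy: each window covers transitions whose onset lies in
#' `[t, t + window_s)`, stepping by `step_s`. Windows with fewer than
#' `min_transitions` events are flagged invalid.
#'
#' @param stream A gaze stream data frame (see [combine_eyes()]).
#' @param layout A `roi_layout`.
#' @param window_s Window length in seconds (default 60).
#' @param step_s Window step in seconds (default 5); must not exceed
#'   `window_s`.
#' @param gap_max_s Dwell-bridging limit passed to
#'   [collapse_to_transitions()].
#' @param min_transitions Minimum events for a valid window (default 5).
#' @return An `index_series` labelled `"visual_entropy"` whose `t_s` are the
#'   window start times, with attribute `n_transitions` (events per window).
#' @export
entropy_series <- function(stream, layout, window_s = 60, step_s = 5,
                           gap_max_s = 1, min_transitions = 5) {
  if (window_s < step_s) {
    stop("entropy series: window_s must be at least step_s", call. = FALSE)
  }
  layout <- roi_layout(as.data.frame(layout))
  mono <- combine_eyes(stream)
  roi <- assign_roi(mono, layout)
  ev <- collapse_to_transitions(mono$t_s, roi, gap_max_s)
  t0 <- min(stream$t_s)
  t_end <- max(stream$t_s)
  if (t_end - t0 >= window_s) {
    starts <- seq(t0, t_end - window_s, by = step_s)
  } else {
    starts <- t0 # single shrunk window over the whole (short) stream
  }
  ids <- layout$id
  n_tr <- integer(length(starts))
  vals <- rep(NA_real_, length(starts))
  ev_t <- ev$t_s
  ord <- order(ev_t)
  ev <- ev[ord, , drop = FALSE]
  ev_t <- ev_t[ord]
  for (k in seq_along(starts)) {
    lo <- findInterval(starts[k], ev_t, left.open = TRUE) + 1L
    hi <- findInterval(starts[k] + window_s, ev_t, left.open = TRUE)
    if (hi >= lo) {
      sel <- ev[lo:hi, , drop = FALSE]
      n_tr[k] <- nrow(sel)
      vals[k] <- visual_entropy(transition_matrix(sel, ids))
    }
  }
  series <- index_series(starts, vals, step_s, "visual_entropy",
                         flagged = n_tr < min_transitions, resample = "grid")
  attr(series, "n_transitions") <- n_tr
  series
}
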