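#' Min-max normalization of an index series
#'
#' Rescales values to `[0, 1]` by `(v - min) / (max - min)`. Flagged points
#' are excluded from the min/max computation but transformed with the same
#' affine map and left flagged.
#'
#' @param series An `index_series` with at least two distinct valid values.
#' @return The normalized `index_series`.
#' @export
minmax_normalize <- function(series) {
  stopifnot(inherits(series, "index_series"))
  v <- series_valid_values(series)
  if (length(v) < 2L) {
    stop("normalization: series needs at least two valid values", call. = FALSE)
  }
  rng <- range(v)
  if (diff(rng) == 0) {
    stop("normalization: constant series has no defined min-max scaling",
         call. = FALSE)
  }
  index_series(series$t_s, (series$value - rng[1L]) / diff(rng),
               series$step_s, series$label, flagged = series$flagged,
               resample = series$resample)
}

# Internal: resample one series onto a given grid, honouring its resampling
# convention; flagged points become NA.
resample_to_grid <- function(series, grid) {
  v <- series$value
  v[series$flagged] <- NA_real_
  if (series$resample == "locf") {
    idx <- findInterval(grid, series$t_s)
    out <- c(NA_real_, v)[idx + 1L]
    # do not carry the last value beyond its grid cell
    out[grid >= series$t_s[length(series$t_s)] + series$step_s] <- NA_real_
    out
  } else {
    m <- match(round(grid * 1e6), round(series$t_s * 1e6))
    v[m]
  }
}

# Internal: coverage end of a series (end of its last grid cell).
series_cover_end <- function(series) {
  series$t_s[length(series$t_s)] + series$step_s
}

#' Align two index series on a common grid
#'
#' Both series are resampled onto a shared `step_s` grid over their time
#' overlap: step-valued series (task index, click bins) by last observation
#' carried forward, natively gridded series by exact stamp matching. Grid
#' points where either series is flagged or undefined are dropped pairwise.
#'
#' @param a,b `index_series` objects with overlapping spans.
#' @param step_s Common grid step in seconds (default 5).
#' @return List with elements `a` and `b`: the two series restricted to the
#'   common valid grid points (identical `t_s`).
#' @export
align_series <- function(a, b, step_s = 5) {
  stopifnot(inherits(a, "index_series"), inherits(b, "index_series"))
  lo <- max(a$t_s[1L], b$t_s[1L])
  hi <- min(series_cover_end(a), series_cover_end(b)) - step_s
  lo <- ceiling(lo / step_s) * step_s
  if (hi < lo) stop("alignment: series do not overlap in time", call. = FALSE)
  grid <- seq(lo, hi, by = step_s)
  va <- resample_to_grid(a, grid)
  vb <- resample_to_grid(b, grid)
  keep <- is.finite(va) & is.finite(vb)
  list(
    a = index_series(grid[keep], va[keep], step_s, a$label, resample = "grid"),
    b = index_series(grid[keep], vb[keep], step_s, b$label, resample = "grid")
  )
}

#' Convex fusion weights for two measures
#'
#' @param w_eeg Weight of the first (EEG-index) component, in `[0, 1]`.
#' @param w_entropy Weight of the second (visual-entropy) component; the two
#'   must sum to 1.
#' @return A `fusion_weights` list.
#' @export
fusion_weights <- function(w_eeg = 0.5, w_entropy = 1 - w_eeg) {
  if (w_eeg < 0 || w_eeg > 1 || w_entropy < 0 || w_entropy > 1 ||
      abs(w_eeg + w_entropy - 1) > 1e-8) {
    stop("fusion weights must lie in [0, 1] and sum to 1", call. = FALSE)
  }
  structure(list(w_eeg = w_eeg, w_entropy = w_entropy),
            class = "fusion_weights")
}

#' Weighted fusion of two aligned, normalized series
#'
#' Pointwise convex combination `w_eeg * a + w_entropy * b`. Inputs must be
#' on identical time grids (use [align_series()]) and are expected to be
#' min-max normalized, so the fused values stay in `[0, 1]`.
#'
#' @param a,b Aligned `index_series` objects.
#' @param w A [fusion_weights()] object; `w_eeg` weights `a`, `w_entropy`
#'   weights `b`.
#' @param label Label of the fused series.
#' @return The fused `index_series`.
#' @export
fuse_series <- function(a, b, w = fusion_weights(0.5, 0.5), label = "fused") {
  stopifnot(inherits(a, "index_series"), inherits(b, "index_series"),
            inherits(w, "fusion_weights"))
  if (length(a$t_s) != length(b$t_s) ||
      any(abs(a$t_s - b$t_s) > 1e-9)) {
    stop("fusion: series must be aligned on an identical grid", call. = FALSE)
  }
  index_series(a$t_s, w$w_eeg * a$value + w$w_entropy * b$value, a$step_s,
               label, flagged = a$flagged | b$flagged, resample = "grid")
}

#' Pearson product-moment correlation coefficient
#'
#' @param x,y Paired numeric vectors (`NA` pairs removed); at least three
#'   complete pairs and non-constant on both sides.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) {
    stop("correlation: x and y must be paired", call. = FALSE)
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3L) {
    stop("correlation: need at least 3 complete pairs", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation: undefined for a constant input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Z-normalized per-phase means of an index series
#'
#' Per-phase mean of the valid points, then centring/scaling across the
#' included phases to mean 0 and (sample) standard deviation 1 — the
#' participant-level normalization used before the phase ANOVA. A degenerate
#' all-equal set of phase means yields all-zero z-scores with a warning.
#'
#' @param series An `index_series`.
#' @param schedule A `phase_schedule`.
#' @param phases Phase labels to include (default: all phases overlapping
#'   the series).
#' @param participant,measure Optional identifying labels carried through.
#' @return A `phase_summary` data frame with columns `participant`,
#'   `measure`, `phase`, `mean`, `z`.
#' @export
zscore_phase_means <- function(series, schedule, phases = NULL,
                               participant = "", measure = series$label) {
  stopifnot(inherits(series, "index_series"),
            inherits(schedule, "phase_schedule"))
  if (is.null(phases)) phases <- schedule$phase
  rows <- match(phases, schedule$phase)
  if (anyNA(rows)) {
    stop("phase means: unknown phase label(s): ",
         paste(phases[is.na(rows)], collapse = ", "), call. = FALSE)
  }
  m <- vapply(rows, function(r) {
    series_window_mean(series, schedule$start_s[r], schedule$end_s[r])
  }, numeric(1))
  if (anyNA(m)) {
    stop("phase means: phase with no valid samples: ",
         paste(phases[is.na(m)], collapse = ", "), call. = FALSE)
  }
  s <- stats::sd(m)
  if (!is.finite(s) || s == 0) {
    warning("phase means are constant; z-scores set to 0")
    z <- rep(0, length(m))
  } else {
    z <- (m - mean(m)) / s
  }
  out <- data.frame(participant = participant, measure = measure,
                    phase = phases, mean = m, z = z,
                    stringsAsFactors = FALSE)
  class(out) <- c("phase_summary", "data.frame")
  out
}

#' One-way analysis of variance
#'
#' Plain one-way fixed-effects ANOVA over independent groups (fitted with
#' `stats::aov`): between/within sum-of-squares decomposition,
#' `F = MSB / MSW`, p-value from the F distribution.
#'
#' @param groups List of numeric vectors, one per group (at least two
#'   groups of at least two values each).
#' @return An `anova_result` list: `F`, `df_between`, `df_within`, `p`,
#'   `means`, `se` (pooled standard error per group mean), `n`.
#' @export
oneway_anova <- function(groups) {
  groups <- lapply(groups, function(g) g[is.finite(g)])
  if (length(groups) < 2L || any(vapply(groups, length, 1L) < 2L)) {
    stop("anova: need at least two groups of at least two values", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  labels <- if (is.null(names(groups))) {
    paste0("group", seq_along(groups))
  } else {
    names(groups)
  }
  g <- factor(rep(labels, vapply(groups, length, 1L)), levels = labels)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  if (ssw <= 1e-12 * max(stats::var(values), .Machine$double.xmin)) {
    stop("anova: zero within-group variance everywhere", call. = FALSE)
  }
  fit <- stats::aov(values ~ g)
  sm <- summary(fit)[[1L]]
  msw <- sm[["Mean Sq"]][2L]
  if (!is.finite(msw) || msw <= 0) {
    stop("anova: zero within-group variance everywhere", call. = FALSE)
  }
  n_i <- vapply(groups, length, 1L)
  res <- list(
    F = sm[["F value"]][1L],
    df_between = sm[["Df"]][1L],
    df_within = sm[["Df"]][2L],
    p = sm[["Pr(>F)"]][1L],
    means = vapply(groups, mean, numeric(1)),
    se = sqrt(msw / n_i),
    n = n_i,
    fit = fit
  )
  names(res$means) <- names(res$se) <- names(res$n) <- labels
  class(res) <- "anova_result"
  res
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  for (i in seq_along(x$means)) {
    cat(sprintf("  %s: M = %.4g, SE = %.4g (n = %d)\n",
                names(x$means)[i], x$means[i], x$se[i], x$n[i]))
  }
  invisible(x)
}

#' Tukey HSD post-hoc pairwise comparisons
#'
#' Studentized-range comparisons of all group pairs at level `alpha`, using
#' the pooled within-group mean square (via `stats::TukeyHSD`).
#'
#' @param groups List of numeric vectors (as for [oneway_anova()]).
#' @param alpha Significance level (default 0.05).
#' @return A `tukey_result` data frame with columns `group_a`, `group_b`,
#'   `diff` (mean of `group_b` minus mean of `group_a`), `p_adj`,
#'   `significant`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  an <- oneway_anova(groups)
  labels <- names(an$means)
  safe <- paste0("g", seq_along(labels)) # avoid '-' parsing issues in names
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(safe, an$n), levels = safe)
  fit <- stats::aov(values ~ g)
  tk <- stats::TukeyHSD(fit)$g
  parts <- strsplit(rownames(tk), "-", fixed = TRUE)
  ia <- match(vapply(parts, `[`, "", 2L), safe)
  ib <- match(vapply(parts, `[`, "", 1L), safe)
  out <- data.frame(
    group_a = labels[ia],
    group_b = labels[ib],
    diff = tk[, "diff"],
    p_adj = tk[, "p adj"],
    significant = tk[, "p adj"] < alpha,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("tukey_result", "data.frame")
  out
}

#' Cross-participant pairwise correlation summary
#'
#' For every pair of features, the per-participant Pearson correlation is
#' computed on pairwise-complete points, then summarized across participants
#' by mean and sample (n-1) standard deviation. Participants lacking a
#' feature, or with fewer than three complete pairs or a constant feature for
#' a pair, are omitted from that pair with a warning. With a single
#' participant the standard deviation is reported as `NA`.
#'
#' @param features List with one element per participant; each element is a
#'   named list of equal-length numeric feature vectors on a common grid
#'   (`NA` marks invalid points).
#' @return List with `summary` (data frame: `feature_a`, `feature_b`,
#'   `mean_cc`, `sd_cc`, `n_participants`) and `by_participant` (long data
#'   frame: `pair`, `participant`, `cc`).
#' @export
correlation_table <- function(features) {
  if (length(features) < 1L) {
    stop("correlation table: need at least one participant", call. = FALSE)
  }
  if (is.null(names(features))) {
    names(features) <- paste0("P", seq_along(features))
  }
  feat_names <- names(features[[1L]])
  pairs <- utils::combn(feat_names, 2L)
  long <- list()
  summ <- list()
  for (k in seq_len(ncol(pairs))) {
    fa <- pairs[1L, k]
    fb <- pairs[2L, k]
    ccs <- rep(NA_real_, length(features))
    for (p in seq_along(features)) {
      xa <- features[[p]][[fa]]
      xb <- features[[p]][[fb]]
      if (is.null(xa) || is.null(xb)) {
        warning(sprintf("participant %s lacks feature pair %s/%s; omitted",
                        names(features)[p], fa, fb))
        next
      }
      ok <- is.finite(xa) & is.finite(xb)
      if (sum(ok) < 3L || stats::sd(xa[ok]) == 0 || stats::sd(xb[ok]) == 0) {
        warning(sprintf("participant %s has a degenerate %s/%s pair; omitted",
                        names(features)[p], fa, fb))
        next
      }
      ccs[p] <- stats::cor(xa[ok], xb[ok])
    }
    ok_cc <- is.finite(ccs)
    long[[k]] <- data.frame(
      pair = paste(fa, fb, sep = "~"), participant = names(features),
      cc = ccs, stringsAsFactors = FALSE
    )
    summ[[k]] <- data.frame(
      feature_a = fa, feature_b = fb,
      mean_cc = if (any(ok_cc)) mean(ccs[ok_cc]) else NA_real_,
      sd_cc = if (sum(ok_cc) > 1L) stats::sd(ccs[ok_cc]) else NA_real_,
      n_participants = sum(ok_cc),
      stringsAsFactors = FALSE
    )
  }
  list(summary = do.call(rbind, summ), by_participant = do.call(rbind, long))
}
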