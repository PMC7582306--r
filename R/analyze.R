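# Internal: resample several index series onto one common step_s grid over
# the intersection of their spans. Flagged points become NA; no row is
# dropped here (correlation uses pairwise deletion).
align_features <- function(series_list, step_s = 5) {
  lo <- max(vapply(series_list, function(s) s$t_s[1L], numeric(1)))
  hi <- min(vapply(series_list, series_cover_end, numeric(1))) - step_s
  lo <- ceiling(lo / step_s) * step_s
  if (hi < lo) stop("alignment: series do not overlap in time", call. = FALSE)
  grid <- seq(lo, hi, by = step_s)
  vals <- vapply(series_list, resample_to_grid, numeric(length(grid)),
                 grid = grid)
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = length(grid))
  colnames(vals) <- names(series_list)
  list(t_s = grid, values = vals)
}

# Internal: min-max scale a numeric vector to [0, 1] (NAs passed through);
# returns all-NA with a warning if degenerate.
minmax_vec <- function(v, label = "") {
  ok <- is.finite(v)
  if (sum(ok) < 2L || diff(range(v[ok])) == 0) {
    warning(sprintf("feature '%s' is constant; min-max normalization skipped",
                    label))
    return(rep(NA_real_, length(v)))
  }
  (v - min(v[ok])) / diff(range(v[ok]))
}

#' Analyze one session end to end
#'
#' Runs the full measurement chain on one participant's streams: the EEG
#' theta/alpha index, the windowed visual entropy, the secondary-task index
#' and the binned controller-input count; aligns the four measures on a
#' common 5-s grid; min-max normalizes them; forms the fused physiological
#' measure (EEG index + visual entropy) and fused objective measure (task
#' index + control input) as weighted sums; and computes the six-feature
#' pairwise correlations and the per-phase normalized means.
#'
#' @param bundle A `session_bundle` from [simulate_session()], or an
#'   equivalent list with elements `schedule`, `eeg`, `gaze`, `uav_logs`,
#'   `clicks` (and a `config` carrying the ROI layout, unless `roi` is
#'   given).
#' @param weights [fusion_weights()] for the physiological fusion
#'   (`w_eeg` / `w_entropy`), default 50/50.
#' @param obj_weights [fusion_weights()] for the objective fusion (task
#'   index weighted by `w_eeg`, control input by `w_entropy`); defaults to
#'   `weights`.
#' @param roi Optional `roi_layout`; defaults to the layout in
#'   `bundle$config$gaze$roi_layout`.
#' @param step_s Common alignment grid step in seconds (default 5).
#' @param click_bin_s Controller-input bin width in seconds (default 120).
#' @param participant Participant label carried into the summaries.
#' @param ... Further arguments passed to [compute_eeg_index_series()].
#' @return An `session_analysis` list: the four measure series, the aligned
#'   feature matrix (`aligned$t_s`, `aligned$values` with the six feature
#'   columns), `features` (named list form), `correlations` (single
#'   participant) and `phase_summary`.
#' @export
analyze_session <- function(bundle, weights = fusion_weights(0.5, 0.5),
                            obj_weights = weights, roi = NULL, step_s = 5,
                            click_bin_s = 120, participant = "P1", ...) {
  if (is.null(roi)) roi <- bundle$config$gaze$roi_layout
  span <- schedule_span(bundle$schedule)

  eeg_idx <- compute_eeg_index_series(bundle$eeg, ...)
  vent <- entropy_series(bundle$gaze, roi, step_s = step_s)
  task <- task_index_series(bundle$uav_logs, step_s = step_s, t_range = span)
  clk <- click_count_series(bundle$clicks, bin_s = click_bin_s,
                            t_range = span)

  al <- align_features(list(eeg_index = eeg_idx, visual_entropy = vent,
                            task_index = task, control_input = clk), step_s)
  norm <- al$values
  for (j in seq_len(ncol(norm))) {
    norm[, j] <- minmax_vec(norm[, j], colnames(norm)[j])
  }
  fused_phys <- weights$w_eeg * norm[, "eeg_index"] +
    weights$w_entropy * norm[, "visual_entropy"]
  fused_obj <- obj_weights$w_eeg * norm[, "task_index"] +
    obj_weights$w_entropy * norm[, "control_input"]
  feat_mat <- cbind(norm, fused_phys = fused_phys, fused_obj = fused_obj)
  features <- stats::setNames(
    lapply(seq_len(ncol(feat_mat)), function(j) feat_mat[, j]),
    colnames(feat_mat))

  cors <- correlation_table(stats::setNames(list(features), participant))

  ps <- rbind(
    zscore_phase_means(eeg_idx, bundle$schedule, participant = participant),
    zscore_phase_means(vent, bundle$schedule, participant = participant),
    zscore_phase_means(task, bundle$schedule, phases = mission_phases(),
                       participant = participant),
    zscore_phase_means(clk, bundle$schedule, phases = mission_phases(),
                       participant = participant)
  )

  structure(
    list(eeg_index = eeg_idx, visual_entropy = vent, task_index = task,
         control_input = clk,
         aligned = list(t_s = al$t_s, values = feat_mat),
         features = features, correlations = cors, phase_summary = ps,
         weights = weights, obj_weights = obj_weights,
         participant = participant, schedule = bundle$schedule,
         ratings = bundle$ratings),
    class = "session_analysis"
  )
}

#' @export
print.session_analysis <- function(x, ...) {
  cat(sprintf("session_analysis '%s': %d aligned grid points, %d features\n",
              x$participant, length(x$aligned$t_s), ncol(x$aligned$values)))
  print(x$correlations$summary, row.names = FALSE)
  invisible(x)
}

#' Simulate and analyze a multi-participant study
#'
#' Generates `n_participants` independent synthetic sessions (one derived
#' seed per participant), analyzes each, and reproduces the study-level
#' statistics: per-measure one-way ANOVA and Tukey HSD across the mission
#' phases (participant phase means as independent observations, giving the
#' `F(2, 3n - 3)` layout), the EEG index additionally over all five phases,
#' and the cross-participant pairwise correlation summary.
#'
#' @param n_participants Number of synthetic participants (default 5).
#' @param config Base [session_config()]; participant seeds are derived from
#'   its master seed.
#' @param weights,obj_weights Fusion weights, as in [analyze_session()].
#' @param ... Passed to [analyze_session()].
#' @return A `study_result` list: `analyses` (per participant),
#'   `phase_summary`, `anova` (data frame over measures), `tukey` (named
#'   list of `tukey_result`s), `correlations`.
#' @export
run_study <- function(n_participants = 5, config = session_config(),
                      weights = fusion_weights(0.5, 0.5),
                      obj_weights = weights, ...) {
  stopifnot(n_participants >= 1)
  analyses <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    cfg_p <- config
    cfg_p$seed <- as.integer((as.numeric(config$seed) + 7907 * p) %% 2147483647)
    bundle <- simulate_session(cfg_p)
    analyses[[p]] <- analyze_session(bundle, weights = weights,
                                     obj_weights = obj_weights,
                                     participant = sprintf("P%d", p), ...)
  }
  names(analyses) <- vapply(analyses, `[[`, "", "participant")

  ps <- do.call(rbind, lapply(analyses, `[[`, "phase_summary"))
  rownames(ps) <- NULL

  # groups of per-participant values, one group per phase
  z_groups <- function(measure, phases) {
    lapply(stats::setNames(phases, phases), function(ph) {
      vapply(analyses, function(a) {
        s <- a$phase_summary
        s$z[s$measure == measure & s$phase == ph]
      }, numeric(1))
    })
  }
  rating_groups <- function(col) {
    lapply(stats::setNames(mission_phases(), mission_phases()), function(ph) {
      vapply(analyses, function(a) {
        a$ratings[[col]][a$ratings$phase == ph]
      }, numeric(1))
    })
  }
  group_sets <- list(
    subjective_mwl = rating_groups("mwl"),
    subjective_sa = rating_groups("sa"),
    task_index = z_groups("task_index", mission_phases()),
    control_input = z_groups("control_input", mission_phases()),
    eeg_index_phases_1_5 = z_groups("eeg_index", phase_labels()),
    eeg_index_phases_1_3 = z_groups("eeg_index", mission_phases()),
    visual_entropy = z_groups("visual_entropy", mission_phases())
  )
  anova_rows <- list()
  tukeys <- list()
  for (m in names(group_sets)) {
    an <- tryCatch(oneway_anova(group_sets[[m]]), error = function(e) NULL)
    if (is.null(an)) next
    anova_rows[[m]] <- data.frame(
      measure = m, F = an$F, df1 = an$df_between, df2 = an$df_within,
      p = an$p, stringsAsFactors = FALSE)
    tukeys[[m]] <- tukey_hsd(group_sets[[m]])
  }
  cors <- correlation_table(lapply(analyses, `[[`, "features"))

  structure(
    list(analyses = analyses, phase_summary = ps,
         anova = do.call(rbind, c(anova_rows, list(make.row.names = FALSE))),
         tukey = tukeys, correlations = cors),
    class = "study_result"
  )
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result: %d participants\n", length(x$analyses)))
  cat("ANOVA across mission phases:\n")
  print(x$anova, row.names = FALSE)
  cat("Cross-participant correlations (mean +/- SD):\n")
  print(x$correlations$summary, row.names = FALSE)
  invisible(x)
}
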