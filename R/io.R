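# CSV schemas (header row, UTF-8, '.' decimal, seconds from session start):
#   eeg.csv       t_s + one column per channel (microvolts)
#   gaze.csv      t_s, left_x, left_y, left_valid, right_x, right_y,
#                 right_valid, blink
#   uav_logs.csv  t_s, uav_id, nav_acc_m, comm_pct, fuel_onboard,
#                 fuel_needed, autopilot_hold, in_team, sensors_active
#   clicks.csv    t_s, button
#   ratings.csv   phase, mwl, sa
#   truth.csv     t_s, workload
#   rois.csv      id, x_min, y_min, x_max, y_max, priority

session_stream_files <- c("eeg.csv", "gaze.csv", "uav_logs.csv",
                          "clicks.csv", "ratings.csv", "truth.csv")

fwrite_csv <- function(df, path) {
  data.table::fwrite(df, path, sep = ",", quote = FALSE, na = "NA")
  invisible(path)
}

fread_csv <- function(path) {
  as.data.frame(data.table::fread(path, sep = ",", header = TRUE,
                                  na.strings = "NA"))
}

#' Write all streams of a session bundle to CSV files
#'
#' Writes the six stream files, the ROI layout (`rois.csv`) and a
#' `config.yaml` with the schedule durations, workload levels and seed, so a
#' directory is a self-contained, re-analyzable session.
#'
#' @param bundle A `session_bundle`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
write_session <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(bundle$eeg$data)
  eeg_df <- data.frame(t_s = bundle$eeg$t0_s + (0:(n - 1L)) / bundle$eeg$fs)
  eeg_df <- cbind(eeg_df, as.data.frame(bundle$eeg$data))
  paths <- c(
    fwrite_csv(eeg_df, file.path(dir, "eeg.csv")),
    fwrite_csv(as.data.frame(bundle$gaze), file.path(dir, "gaze.csv")),
    fwrite_csv(as.data.frame(bundle$uav_logs), file.path(dir, "uav_logs.csv")),
    fwrite_csv(as.data.frame(bundle$clicks), file.path(dir, "clicks.csv")),
    fwrite_csv(bundle$ratings, file.path(dir, "ratings.csv")),
    fwrite_csv(data.frame(t_s = bundle$truth$grid_s,
                          workload = bundle$truth$level),
               file.path(dir, "truth.csv")),
    write_roi_csv(bundle$config$gaze$roi_layout, file.path(dir, "rois.csv")),
    write_config_yaml(bundle$config, file.path(dir, "config.yaml"))
  )
  invisible(paths)
}

write_roi_csv <- function(layout, path) {
  layout <- as.data.frame(layout)
  layout$priority <- seq_len(nrow(layout))
  fwrite_csv(layout[, c("id", "x_min", "y_min", "x_max", "y_max", "priority")],
             path)
}

read_roi_csv <- function(path) {
  df <- fread_csv(path)
  if ("priority" %in% names(df)) df <- df[order(df$priority), , drop = FALSE]
  roi_layout(df[, c("id", "x_min", "y_min", "x_max", "y_max")])
}

write_config_yaml <- function(config, path) {
  strip <- function(x, drop) x[setdiff(names(x), drop)]
  y <- list(
    schedule = list(durations_s = as.numeric(config$schedule$end_s -
                                               config$schedule$start_s)),
    levels = as.numeric(config$levels),
    seed = config$seed,
    profile_step_s = config$profile_step_s,
    eeg = strip(config$eeg, character(0)),
    gaze = strip(config$gaze, "roi_layout"),
    uav = config$uav,
    clicks = config$clicks,
    ratings = config$ratings
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Load a session configuration from a YAML file
#'
#' The document mirrors the [session_config()] arguments: top-level keys
#' `schedule` (with `durations_s`), `levels`, `seed`, `profile_step_s` and
#' the per-stream blocks `eeg`, `gaze`, `uav`, `clicks`, `ratings`. Unknown
#' top-level keys are an error naming the key. A `gaze.roi_file` entry points
#' to a `rois.csv` layout file (resolved relative to the YAML file).
#'
#' @param path Path to the YAML document.
#' @return A validated `session_config`.
#' @export
config_from_yaml <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  y <- yaml::read_yaml(path)
  known <- c("schedule", "levels", "seed", "profile_step_s",
             "eeg", "gaze", "uav", "clicks", "ratings")
  extra <- setdiff(names(y), known)
  if (length(extra)) {
    stop("config error in `", extra[1L], "`: unknown configuration key",
         call. = FALSE)
  }
  schedule <- if (!is.null(y$schedule$durations_s)) {
    make_phase_schedule(as.numeric(y$schedule$durations_s))
  } else {
    make_phase_schedule()
  }
  gaze <- if (is.null(y$gaze)) list() else y$gaze
  if (!is.null(gaze$roi_file)) {
    gaze$roi_layout <- read_roi_csv(file.path(dirname(path), gaze$roi_file))
    gaze$roi_file <- NULL
  }
  if (!is.null(gaze$roi_layout) && !inherits(gaze$roi_layout, "roi_layout")) {
    gaze$roi_layout <- roi_layout(as.data.frame(
      do.call(rbind.data.frame, gaze$roi_layout)))
  }
  session_config(
    schedule = schedule,
    levels = if (is.null(y$levels)) c(0.05, 0.2, 0.55, 0.9, 0.15) else
      as.numeric(y$levels),
    seed = if (is.null(y$seed)) 1L else y$seed,
    profile_step_s = if (is.null(y$profile_step_s)) 5 else y$profile_step_s,
    eeg = if (is.null(y$eeg)) list() else y$eeg,
    gaze = gaze,
    uav = if (is.null(y$uav)) list() else y$uav,
    clicks = if (is.null(y$clicks)) list() else y$clicks,
    ratings = if (is.null(y$ratings)) list() else y$ratings
  )
}

#' Simulate a session and write it to disk
#'
#' @param config A `session_config`, a path to a YAML configuration, or
#'   `NULL` for the defaults.
#' @param seed Optional master-seed override.
#' @param out_dir Output directory for the stream CSVs.
#' @return Invisibly, the written file paths.
#' @export
run_simulate <- function(config = NULL, seed = NULL, out_dir) {
  if (is.null(config)) {
    config <- session_config()
  } else if (is.character(config)) {
    config <- config_from_yaml(config)
  }
  validate_session_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  bundle <- simulate_session(config)
  write_session(bundle, out_dir)
}

#' Read session streams back from a directory
#'
#' @param dir Directory written by [write_session()] (or following the same
#'   schemas).
#' @param partial If `TRUE`, missing stream files yield `NULL` elements
#'   instead of an error.
#' @return A `session_bundle`-like list (without generator config; the ROI
#'   layout and reconstructed schedule are attached).
#' @export
read_session <- function(dir, partial = FALSE) {
  need <- function(f) {
    p <- file.path(dir, f)
    if (!file.exists(p)) {
      if (partial) return(NULL)
      stop("missing stream file: ", f, call. = FALSE)
    }
    p
  }
  cfg_path <- file.path(dir, "config.yaml")
  schedule <- if (file.exists(cfg_path)) {
    y <- yaml::read_yaml(cfg_path)
    make_phase_schedule(as.numeric(y$schedule$durations_s))
  } else {
    make_phase_schedule()
  }
  roi_path <- file.path(dir, "rois.csv")
  roi <- if (file.exists(roi_path)) read_roi_csv(roi_path) else
    default_roi_layout()

  eeg <- NULL
  p <- need("eeg.csv")
  if (!is.null(p)) {
    df <- fread_csv(p)
    fs <- round(1 / stats::median(diff(df$t_s)))
    eeg <- eeg_recording(as.matrix(df[, setdiff(names(df), "t_s"),
                                      drop = FALSE]),
                         fs = fs, t0_s = df$t_s[1L])
  }
  gaze <- NULL
  p <- need("gaze.csv")
  if (!is.null(p)) {
    gaze <- fread_csv(p)
    class(gaze) <- c("gaze_stream", "data.frame")
  }
  uav <- NULL
  p <- need("uav_logs.csv")
  if (!is.null(p)) {
    uav <- fread_csv(p)
    class(uav) <- c("uav_log_set", "data.frame")
  }
  clicks <- NULL
  p <- need("clicks.csv")
  if (!is.null(p)) clicks <- fread_csv(p)
  ratings <- NULL
  p <- need("ratings.csv")
  if (!is.null(p)) ratings <- fread_csv(p)
  truth <- NULL
  tp <- file.path(dir, "truth.csv")
  if (file.exists(tp)) truth <- fread_csv(tp)

  list(schedule = schedule, roi = roi, eeg = eeg, gaze = gaze,
       uav_logs = uav, clicks = clicks, ratings = ratings, truth = truth)
}

# Internal: per-phase groups of block means of a series (used for the
# within-session phase ANOVA).
phase_value_blocks <- function(series, schedule, phases = mission_phases(),
                               block_s = 60) {
  lapply(stats::setNames(phases, phases), function(ph) {
    r <- match(ph, schedule$phase)
    starts <- seq(schedule$start_s[r], schedule$end_s[r] - block_s,
                  by = block_s)
    v <- vapply(starts, function(s) series_window_mean(series, s, s + block_s),
                numeric(1))
    v[is.finite(v)]
  })
}

#' Analyze a session directory and write the derived files
#'
#' Reads the stream CSVs, runs each measurement chain and writes:
#' `eeg_index.csv`, `entropy.csv`, `task_index.csv`, `clicks_binned.csv`,
#' plus — when all four streams are present — `phase_summary.csv`,
#' `anova.csv`, `tukey.csv` (within-session phase comparisons on 60-s block
#' means), `correlations.csv` and `correlation_summary.csv`. Record and flag
#' counts are reported per stage via `message()`.
#'
#' @param in_dir Directory holding the stream CSVs.
#' @param out_dir Output directory (defaults to `in_dir`).
#' @param weights,obj_weights [fusion_weights()] for the physiological and
#'   objective fusions.
#' @param partial If `TRUE`, analyze whatever streams are present; if
#'   `FALSE` (default), a missing stream file is an error naming the file.
#' @param phases Phases included in the ANOVA/Tukey comparison (default the
#'   three mission phases).
#' @return Invisibly, the written file paths.
#' @export
run_analyze <- function(in_dir, out_dir = in_dir,
                        weights = fusion_weights(0.5, 0.5),
                        obj_weights = weights, partial = FALSE,
                        phases = mission_phases()) {
  ses <- read_session(in_dir, partial = partial)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  schedule <- ses$schedule
  span <- schedule_span(schedule)
  paths <- character(0)
  series <- list()

  if (!is.null(ses$eeg)) {
    s <- compute_eeg_index_series(ses$eeg)
    series$eeg_index <- s
    message(sprintf("eeg_index: %d windows, %d replaced", length(s$t_s),
                    attr(s, "n_replaced")))
    paths <- c(paths, fwrite_csv(as.data.frame(s),
                                 file.path(out_dir, "eeg_index.csv")))
  }
  if (!is.null(ses$gaze)) {
    s <- entropy_series(ses$gaze, ses$roi)
    series$visual_entropy <- s
    message(sprintf("visual_entropy: %d windows, %d flagged", length(s$t_s),
                    sum(s$flagged)))
    df <- as.data.frame(s)
    df$n_transitions <- attr(s, "n_transitions")
    paths <- c(paths, fwrite_csv(df[, c("t_s", "value", "n_transitions",
                                        "flagged")],
                                 file.path(out_dir, "entropy.csv")))
  }
  if (!is.null(ses$uav_logs)) {
    s <- task_index_series(ses$uav_logs, t_range = span)
    series$task_index <- s
    message(sprintf("task_index: %d grid points from %d records",
                    length(s$t_s), nrow(ses$uav_logs)))
    paths <- c(paths, fwrite_csv(as.data.frame(s)[, c("t_s", "value")],
                                 file.path(out_dir, "task_index.csv")))
  }
  if (!is.null(ses$clicks)) {
    s <- click_count_series(ses$clicks, t_range = span)
    series$control_input <- s
    message(sprintf("control_input: %d bins from %d clicks", length(s$t_s),
                    nrow(ses$clicks)))
    paths <- c(paths, fwrite_csv(as.data.frame(s)[, c("t_s", "value")],
                                 file.path(out_dir, "clicks_binned.csv")))
  }

  if (length(series) == 4L) {
    al <- align_features(series, step_s = 5)
    norm <- al$values
    for (j in seq_len(ncol(norm))) {
      norm[, j] <- minmax_vec(norm[, j], colnames(norm)[j])
    }
    feat <- cbind(
      norm,
      fused_phys = weights$w_eeg * norm[, "eeg_index"] +
        weights$w_entropy * norm[, "visual_entropy"],
      fused_obj = obj_weights$w_eeg * norm[, "task_index"] +
        obj_weights$w_entropy * norm[, "control_input"])
    features <- stats::setNames(
      lapply(seq_len(ncol(feat)), function(j) feat[, j]), colnames(feat))

    ps <- rbind(
      zscore_phase_means(series$eeg_index, schedule, participant = "P1"),
      zscore_phase_means(series$visual_entropy, schedule, participant = "P1"),
      zscore_phase_means(series$task_index, schedule,
                         phases = mission_phases(), participant = "P1"),
      zscore_phase_means(series$control_input, schedule,
                         phases = mission_phases(), participant = "P1"))
    paths <- c(paths, fwrite_csv(ps, file.path(out_dir, "phase_summary.csv")))

    anova_rows <- list()
    tukey_rows <- list()
    for (m in names(series)) {
      gr <- phase_value_blocks(series[[m]], schedule, phases = phases)
      an <- tryCatch(oneway_anova(gr), error = function(e) NULL)
      if (is.null(an)) next
      anova_rows[[m]] <- data.frame(measure = m, F = an$F,
                                    df1 = an$df_between, df2 = an$df_within,
                                    p = an$p, stringsAsFactors = FALSE)
      tk <- tukey_hsd(gr)
      tk <- cbind(measure = m, tk)
      tukey_rows[[m]] <- tk
    }
    paths <- c(paths,
               fwrite_csv(do.call(rbind, anova_rows),
                          file.path(out_dir, "anova.csv")),
               fwrite_csv(do.call(rbind, tukey_rows),
                          file.path(out_dir, "tukey.csv")))

    cors <- correlation_table(list(P1 = features))
    paths <- c(paths,
               fwrite_csv(cors$by_participant,
                          file.path(out_dir, "correlations.csv")),
               fwrite_csv(cbind(
                 pair = paste(cors$summary$feature_a, cors$summary$feature_b,
                              sep = "~"),
                 cors$summary[, c("mean_cc", "sd_cc", "n_participants")]),
                 file.path(out_dir, "correlation_summary.csv")))
  }
  invisible(paths)
}

#' Write a plain-text summary report of a derived file set
#'
#' Summarizes the phase means, ANOVA table, Tukey groupings and the pairwise
#' correlation matrix of an analyzed session directory into `report.txt`.
#'
#' @param out_dir Directory holding the derived CSVs from [run_analyze()].
#' @param phases Optional label describing a phase restriction applied
#'   during analysis (echoed in the report header).
#' @return Invisibly, the report lines (also written to
#'   `out_dir/report.txt`).
#' @export
run_report <- function(out_dir, phases = mission_phases()) {
  need <- function(f) {
    p <- file.path(out_dir, f)
    if (!file.exists(p)) stop("missing derived file: ", f, call. = FALSE)
    fread_csv(p)
  }
  ps <- need("phase_summary.csv")
  an <- need("anova.csv")
  tk <- need("tukey.csv")
  cs <- need("correlation_summary.csv")

  fmt_df <- function(df) utils::capture.output(print(df, row.names = FALSE))
  lines <- c(
    "Mental-workload session report",
    sprintf("Phases compared: %s", paste(phases, collapse = ", ")),
    "",
    "Normalized per-phase means (z across phases):",
    fmt_df(ps),
    "",
    "One-way ANOVA across phases (60-s block means):",
    fmt_df(an),
    "",
    "Tukey HSD pairwise comparisons:",
    fmt_df(tk),
    "",
    "Pairwise correlation summary (all six features):",
    fmt_df(cs)
  )
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(lines)
}
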