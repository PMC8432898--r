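# Session container I/O (delimited-text session directories) and the
# end-to-end pipeline runner.

#' Write a session to a directory of delimited text files
#'
#' A session directory holds `metadata.yaml`, `behavior.csv` (the pose/
#' kinematics table), `traces.csv` (cells x frames, one row per cell, first
#' column the cell id) and, when ground truth is present,
#' `truth_binary.csv` and `truth_rate.csv` in the same layout.
#'
#' @param session a `session` object.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- session$metadata
  arena <- meta$arena
  meta_out <- list(kind = arena$kind, width_cm = arena$width_cm,
                   height_cm = arena$height_cm,
                   track_length_cm = arena$track_length_cm,
                   frame_rate_hz = meta$frame_rate_hz,
                   duration_s = meta$duration_s,
                   n_cells = nrow(session$traces),
                   seed = meta$seed)
  yaml::write_yaml(meta_out, file.path(path, "metadata.yaml"))
  write.csv(as.data.frame(session$behavior), file.path(path, "behavior.csv"),
            row.names = FALSE)
  tr <- data.frame(cell_id = rownames(session$traces), session$traces,
                   check.names = FALSE)
  write.csv(tr, file.path(path, "traces.csv"), row.names = FALSE)
  if (!is.null(session$truth)) {
    write.csv(data.frame(cell_id = rownames(session$traces),
                         session$truth$binary, check.names = FALSE),
              file.path(path, "truth_binary.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a session from a delimited-text session directory
#'
#' Validates the schema on load: the metadata header, behavior table and
#' trace matrix must be present, share the frame count, and carry strictly
#' increasing timestamps; errors name the missing or offending component.
#'
#' @param path session directory written by [write_session()].
#' @return a `session` object.
#' @export
read_session <- function(path) {
  need <- c("metadata.yaml", "behavior.csv", "traces.csv")
  for (f in need) {
    if (!file.exists(file.path(path, f)))
      stop(sprintf("session at '%s' is missing %s", path, f))
  }
  meta <- yaml::read_yaml(file.path(path, "metadata.yaml"))
  behavior <- read.csv(file.path(path, "behavior.csv"),
                       stringsAsFactors = FALSE)
  if (is.null(behavior$t)) stop("behavior.csv is missing column 't'")
  if (any(diff(behavior$t) <= 0))
    stop("behavior.csv timestamps are not strictly increasing")
  tr <- read.csv(file.path(path, "traces.csv"), check.names = FALSE)
  cell_ids <- tr[[1]]
  traces <- as.matrix(tr[, -1, drop = FALSE])
  rownames(traces) <- cell_ids
  if (ncol(traces) != nrow(behavior))
    stop("traces and behavior disagree on frame count")
  arena <- if (identical(meta$kind, "linear_track"))
    arena_spec("linear_track", track_length_cm = meta$track_length_cm)
  else arena_spec("open_field", meta$width_cm, meta$height_cm)
  class(behavior) <- c("behavior_track", "data.frame")
  attr(behavior, "arena") <- arena
  attr(behavior, "frame_rate_hz") <- meta$frame_rate_hz
  truth <- NULL
  tb <- file.path(path, "truth_binary.csv")
  if (file.exists(tb)) {
    tbm <- read.csv(tb, check.names = FALSE)
    truth <- list(binary = as.matrix(tbm[, -1, drop = FALSE]))
  }
  structure(list(
    metadata = list(arena = arena, frame_rate_hz = meta$frame_rate_hz,
                    duration_s = meta$duration_s,
                    n_cells = nrow(traces), seed = meta$seed),
    behavior = behavior, traces = traces, timestamps = behavior$t,
    truth = truth),
    class = "session")
}

#' Run the full analysis pipeline on one session
#'
#' Executes binarization, kinematics/masking, tuning-map estimation,
#' mutual-information significance, per-cell metrics and (optionally)
#' bootstrap decoding in order, writing one CSV per stage plus a run log with
#' all parameters and the seed.
#'
#' @param session a `session` object.
#' @param out_dir output directory.
#' @param config named list overriding defaults: `z_threshold`, `cutoff_hz`,
#'   `velocity_threshold_cm_s`, `n_boot`, `n_shuffles`, `alpha`,
#'   `min_shift_s`, `sigma_bins`, `decode` (logical), `n_bins` (positional
#'   bin override), `cells_per_sample`, `window_s`, `seed`.
#' @return invisibly, a list with the per-stage results (`mi`, `metrics`,
#'   `decoding`, `bins`, `spec`, binarized `session`).
#' @export
run_pipeline <- function(session, out_dir, config = list()) {
  cfg <- modifyList(list(z_threshold = 2, cutoff_hz = 2,
                         velocity_threshold_cm_s = 5, n_boot = 30,
                         n_shuffles = 30, alpha = 0.01, min_shift_s = 30,
                         sigma_bins = 3, decode = TRUE, n_bins = NULL,
                         cells_per_sample = NULL, window_s = NULL,
                         seed = 1),
                    config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fr <- session$metadata$frame_rate_hz
  arena <- session$metadata$arena
  session <- binarize_session(session, cutoff_hz = cfg$cutoff_hz,
                              z_threshold = cfg$z_threshold)
  track <- session$behavior
  if (is.null(track$velocity))
    track <- compute_kinematics(track, fr)
  run <- running_mask(track$velocity, cfg$velocity_threshold_cm_s)
  variable <- if (arena$kind == "open_field") "position2d" else "position1d"
  spec <- binning_spec(variable, arena, n_bins = cfg$n_bins)
  bins <- bin_states(state_values(track, spec), spec, mask = run)
  min_shift <- round(cfg$min_shift_s * fr)
  mi_tab <- population_mi(session$binary, bins, spec, n_boot = cfg$n_boot,
                          n_shuffles = cfg$n_shuffles, alpha = cfg$alpha,
                          min_shift_frames = min_shift, seed = cfg$seed)
  write.csv(mi_tab, file.path(out_dir, "mi_results.csv"), row.names = FALSE)
  metrics <- cell_metrics(session$binary, bins, spec,
                          positions = cbind(track$head_x, track$head_y),
                          mask = run)
  write.csv(metrics, file.path(out_dir, "cell_metrics.csv"),
            row.names = FALSE)
  decoding <- NULL
  if (isTRUE(cfg$decode)) {
    n_cells <- nrow(session$binary)
    cps <- if (is.null(cfg$cells_per_sample)) min(60L, n_cells)
           else cfg$cells_per_sample
    win <- if (is.null(cfg$window_s)) {
      if (arena$kind == "open_field") 1.5 else 0.5
    } else cfg$window_s
    decoding <- rbind(
      bootstrap_decode(session$binary, bins, spec, cells_per_sample = cps,
                       n_boot = cfg$n_boot, shuffle_control = FALSE,
                       window_s = win, frame_rate_hz = fr,
                       min_shift_frames = min_shift, seed = cfg$seed),
      bootstrap_decode(session$binary, bins, spec, cells_per_sample = cps,
                       n_boot = cfg$n_boot, shuffle_control = TRUE,
                       window_s = win, frame_rate_hz = fr,
                       min_shift_frames = min_shift, seed = cfg$seed + 1))
    write.csv(decoding, file.path(out_dir, "decoding.csv"),
              row.names = FALSE)
  }
  log <- c(list(package_version = as.character(utils::packageVersion("septune")),
                arena_kind = arena$kind, frame_rate_hz = fr,
                n_cells = nrow(session$binary),
                n_frames = ncol(session$binary)),
           cfg[!vapply(cfg, is.null, logical(1))])
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  invisible(list(mi = mi_tab, metrics = metrics, decoding = decoding,
                 bins = bins, spec = spec, session = session))
}
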