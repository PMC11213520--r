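#' Experiment configuration
#'
#' Builds the fully-resolved configuration that drives an analysis run. Only
#' four keys are required -- where the data live, which conditions to compare
#' (first condition is the control), the pixel size and the frame interval --
#' everything else defaults to the values used for primary immune-cell
#' timelapse data: an 8-frame sliding window, a debris filter keeping cells
#' with area > 50 um^2 observed for at least 8 timepoints, UMAP/HDBSCAN
#' hyperparameters of 50 neighbours and 500/300 minimum cluster size/samples
#' per timepoint (15 and 15/10 for trajectories), a 200--220 timepoint
#' length filter for sequence comparison, and turn angle and Ripley's K left
#' out of clustering.
#'
#' @param master_path directory containing one folder per condition, each with
#'   one subfolder per replicate.
#' @param conditions character vector of condition folder names; the first is
#'   the control/reference condition.
#' @param pixel_size microns per pixel (> 0).
#' @param frame_interval seconds between frames (> 0).
#' @param window_frames sliding time-window length in frames (>= 2).
#' @param min_area_um2 debris filter: tracks with median contour area less
#'   than or equal to this are removed (strict `>` survives).
#' @param min_track_frames debris filter: tracks observed for fewer frames are
#'   removed. Defaults to `window_frames`.
#' @param excluded_features metric names kept in the feature table but not
#'   used for clustering.
#' @param umap_neighbors_tp,hdbscan_min_cluster_tp,hdbscan_min_samples_tp
#'   per-timepoint behavioural clustering hyperparameters.
#' @param umap_neighbors_traj,hdbscan_min_cluster_traj,hdbscan_min_samples_traj
#'   trajectory clustering hyperparameters.
#' @param traj_len_min,traj_len_max inclusive sequence-length bounds for
#'   trajectory analysis.
#' @param n_boot bootstrap resamples for effect-size statistics.
#' @param rng_seed integer seed controlling every stochastic step.
#' @param arrest_threshold_um_min speed (um/min) below which a window step
#'   counts as arrested.
#' @param ripley_radius_um neighbourhood radius for the spatial density metric.
#' @return an `experiment_config` list with all keys resolved.
#' @seealso [read_experiment_config()] to load one from a YAML file.
#' @export
experiment_config <- function(master_path,
                              conditions,
                              pixel_size,
                              frame_interval,
                              window_frames = 8L,
                              min_area_um2 = 50,
                              min_track_frames = window_frames,
                              excluded_features = c("turn_angle", "ripley_k"),
                              umap_neighbors_tp = 50L,
                              hdbscan_min_cluster_tp = 500L,
                              hdbscan_min_samples_tp = 300L,
                              umap_neighbors_traj = 15L,
                              hdbscan_min_cluster_traj = 15L,
                              hdbscan_min_samples_traj = 10L,
                              traj_len_min = 200L,
                              traj_len_max = 220L,
                              n_boot = 1000L,
                              rng_seed = 1L,
                              arrest_threshold_um_min = 2,
                              ripley_radius_um = 50) {
  if (missing(master_path) || is.null(master_path)) {
    stop_config("configuration is missing required key `master_path`")
  }
  if (missing(conditions) || is.null(conditions) || length(conditions) == 0) {
    stop_config("configuration is missing required key `conditions`")
  }
  if (missing(pixel_size) || is.null(pixel_size)) {
    stop_config("configuration is missing required key `pixel_size`")
  }
  if (missing(frame_interval) || is.null(frame_interval)) {
    stop_config("configuration is missing required key `frame_interval`")
  }
  conditions <- as.character(conditions)
  if (anyDuplicated(conditions)) stop_config("`conditions` must be unique")
  assert_scalar_number(pixel_size, "pixel_size", positive = TRUE)
  assert_scalar_number(frame_interval, "frame_interval", positive = TRUE)
  window_frames <- as.integer(window_frames)
  min_track_frames <- as.integer(min_track_frames)
  if (window_frames < 2L) stop_config("`window_frames` must be >= 2")
  if (window_frames > min_track_frames) {
    stop_config("`window_frames` must be <= `min_track_frames`")
  }
  traj_len_min <- as.integer(traj_len_min)
  traj_len_max <- as.integer(traj_len_max)
  if (traj_len_min > traj_len_max) {
    stop_config("`traj_len_min` must be <= `traj_len_max`")
  }
  cfg <- list(
    master_path = master_path,
    conditions = conditions,
    pixel_size = pixel_size,
    frame_interval = frame_interval,
    window_frames = window_frames,
    min_area_um2 = min_area_um2,
    min_track_frames = min_track_frames,
    excluded_features = as.character(excluded_features %||% character()),
    umap_neighbors_tp = as.integer(umap_neighbors_tp),
    hdbscan_min_cluster_tp = as.integer(hdbscan_min_cluster_tp),
    hdbscan_min_samples_tp = as.integer(hdbscan_min_samples_tp),
    umap_neighbors_traj = as.integer(umap_neighbors_traj),
    hdbscan_min_cluster_traj = as.integer(hdbscan_min_cluster_traj),
    hdbscan_min_samples_traj = as.integer(hdbscan_min_samples_traj),
    traj_len_min = traj_len_min,
    traj_len_max = traj_len_max,
    n_boot = as.integer(n_boot),
    rng_seed = as.integer(rng_seed),
    arrest_threshold_um_min = arrest_threshold_um_min,
    ripley_radius_um = ripley_radius_um
  )
  structure(cfg, class = "experiment_config")
}

#' Read an experiment configuration from a YAML file
#'
#' The file is a declarative key-value document (never executable code); any
#' key absent from the file takes its documented default. Unknown keys raise
#' an error so typos cannot silently change an analysis.
#'
#' @param path path to a YAML file.
#' @return an [experiment_config()] object.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) stop_config(sprintf("config file '%s' does not exist", path))
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop_config("config file is not a key-value document")
  known <- names(formals(experiment_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop_config(sprintf("unknown configuration key(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  cfg <- do.call(experiment_config, raw)
  cfg$source_file <- normalizePath(path)
  cfg
}

#' Write a resolved configuration to YAML (for provenance)
#' @param config an [experiment_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_experiment_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @exportS3Method base::print
print.experiment_config <- function(x, ...) {
  cat("<experiment_config>\n")
  cat("  master_path:", x$master_path, "\n")
  cat("  conditions :", paste(x$conditions, collapse = ", "),
      sprintf("(control = %s)", x$conditions[1]), "\n")
  cat(sprintf("  pixel_size : %g um/px, frame_interval: %g s\n",
              x$pixel_size, x$frame_interval))
  cat(sprintf("  window     : %d frames (%.1f min); debris filter: area > %g um^2, >= %d frames\n",
              x$window_frames, x$window_frames * x$frame_interval / 60,
              x$min_area_um2, x$min_track_frames))
  cat(sprintf("  clustering : tp UMAP nn=%d, HDBSCAN %d/%d | traj UMAP nn=%d, HDBSCAN %d/%d\n",
              x$umap_neighbors_tp, x$hdbscan_min_cluster_tp, x$hdbscan_min_samples_tp,
              x$umap_neighbors_traj, x$hdbscan_min_cluster_traj, x$hdbscan_min_samples_traj))
  cat(sprintf("  sequences  : length %d-%d; n_boot=%d; seed=%d\n",
              x$traj_len_min, x$traj_len_max, x$n_boot, x$rng_seed))
  invisible(x)
}
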