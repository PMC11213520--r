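#' The default morpho-kinetic metric catalogue
#'
#' 28 per-cell per-timepoint metrics in three groups: 13 contour morphology
#' metrics, 13 time-windowed migration metrics and 2 spatial neighbourhood
#' metrics. The catalogue is data: downstream code (scaling, clustering,
#' exports) is driven by this table, so additional metrics can be appended
#' without touching the rest of the pipeline. By default `turn_angle` and
#' `ripley_k` are computed but excluded from clustering.
#'
#' @return a tibble with columns `name`, `group`, `description`.
#' @export
metric_catalogue <- function() {
  tribble_ <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    tibble(name = m[, 1], group = m[, 2], description = m[, 3])
  }
  tribble_(
    "area", "morphology", "contour area (um^2, shoelace)",
    "perimeter", "morphology", "contour perimeter (um)",
    "circularity", "morphology", "4*pi*A/P^2; 1 for a circle",
    "eccentricity", "morphology", "eccentricity of the second-moment equivalent ellipse",
    "aspect_ratio", "morphology", "major/minor axis length of the equivalent ellipse",
    "major_axis_length", "morphology", "major axis of the equivalent ellipse (um)",
    "minor_axis_length", "morphology", "minor axis of the equivalent ellipse (um)",
    "solidity", "morphology", "area / convex hull area",
    "extent", "morphology", "area / axis-aligned bounding-box area",
    "equivalent_diameter", "morphology", "sqrt(4A/pi) (um)",
    "orientation", "morphology", "major-axis angle in (-pi/2, pi/2], image coords",
    "bbox_area", "morphology", "axis-aligned bounding-box area (um^2)",
    "convex_area", "morphology", "convex hull area (um^2)",
    "displacement", "migration", "step length into the current frame (um)",
    "speed", "migration", "instantaneous speed (um/min)",
    "cumulative_length", "migration", "path length over the trailing window (um)",
    "euclidean_distance", "migration", "net displacement over the window (um)",
    "directedness", "migration", "endpoint directionality: net/path length, in [0,1]",
    "outreach_ratio", "migration", "max excursion from window start / path length, in [0,1]",
    "msd", "migration", "mean squared displacement at lag floor(W/2) within the window (um^2)",
    "max_displacement", "migration", "max excursion from window start (um)",
    "turn_angle", "migration", "absolute angle between successive steps (rad)",
    "arrest_coefficient", "migration", "fraction of window steps slower than the arrest threshold",
    "velocity_x", "migration", "net x velocity over the window (um/min)",
    "velocity_y", "migration", "net y velocity over the window (um/min)",
    "mean_window_speed", "migration", "mean step speed over the window (um/min)",
    "ripley_k", "spatial", "neighbours within radius / global intensity (um^2)",
    "nn_distance", "spatial", "distance to the nearest other cell in frame (um)"
  )
}

#' Morphology metrics of a single cell contour
#'
#' Closed-form polygon morphometrics: area and perimeter from the shoelace
#' formulas, an equivalent ellipse from the exact second central moments of
#' the polygon lamina (eccentricity, aspect ratio, axis lengths, orientation),
#' solidity against the convex hull, and bounding-box statistics. Axis lengths
#' follow the usual equivalent-ellipse convention (`4*sqrt(eigenvalue)`), so a
#' circle of radius r has `major_axis_length == 2r`.
#'
#' @param contour a two-column vertex matrix (um), at least 3 vertices,
#'   positive area.
#' @return a named numeric vector of the 13 morphology metrics.
#' @examples
#' theta <- seq(0, 2 * pi, length.out = 91)[-91]
#' circle <- cbind(10 * cos(theta), 10 * sin(theta))
#' contour_morphology(circle)[c("area", "circularity", "eccentricity")]
#' @export
contour_morphology <- function(contour) {
  p <- validate_contour(contour)
  a <- polygon_area(p)
  if (a <= 0) stop_data("degenerate contour: area <= 0")
  per <- polygon_perimeter(p)
  m <- polygon_moments(p)
  cov <- matrix(c(m$var_x, m$cov_xy, m$cov_xy, m$var_y), 2)
  ev <- eigen(cov, symmetric = TRUE)
  l1 <- max(ev$values[1], 0); l2 <- max(ev$values[2], 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  ecc <- if (l1 > 0) sqrt(pmax(1 - l2 / l1, 0)) else 0
  v <- ev$vectors[, 1]
  orientation <- atan2(v[2], v[1])
  if (orientation <= -pi / 2) orientation <- orientation + pi
  if (orientation > pi / 2) orientation <- orientation - pi
  bbox <- (max(p[, 1]) - min(p[, 1])) * (max(p[, 2]) - min(p[, 2]))
  hull <- convex_hull_area(p)
  c(
    area = a,
    perimeter = per,
    circularity = 4 * pi * a / per^2,
    eccentricity = ecc,
    aspect_ratio = if (minor > 0) major / minor else Inf,
    major_axis_length = major,
    minor_axis_length = minor,
    solidity = a / hull,
    extent = if (bbox > 0) a / bbox else 1,
    equivalent_diameter = sqrt(4 * a / pi),
    orientation = orientation,
    bbox_area = bbox,
    convex_area = hull
  )
}

#' Time-windowed migration metrics for one track
#'
#' For every frame of a track, kinematic metrics are computed over the
#' *trailing* window of up to `window_frames` frames ending at that frame
#' (causal, clipped at the track start; `window_complete` flags frames with a
#' full window). Speeds are reported in um/min regardless of the frame
#' interval. `directedness` is net displacement over path length and
#' `outreach_ratio` the maximum excursion from the window start over path
#' length; both are 0 when the path length is 0 and never exceed 1. The MSD
#' scalar averages squared displacements at lag `floor(window_frames / 2)`
#' over all in-window pairs (shorter partial windows fall back to their
#' largest available lag). A single-frame track yields all-zero metrics with
#' `window_complete = FALSE`.
#'
#' @param track data frame with columns `frame`, `x_um`, `y_um` (one track,
#'   strictly increasing frames).
#' @param window_frames window length W in frames (>= 2).
#' @param frame_interval seconds between consecutive frames.
#' @param arrest_threshold speed (um/min) below which a step counts as
#'   arrested.
#' @return a tibble with one row per input frame: the 13 migration metrics
#'   plus `frame` and `window_complete`.
#' @export
window_kinematics <- function(track, window_frames = 8L, frame_interval = 40,
                              arrest_threshold = 2) {
  assert_scalar_number(frame_interval, "frame_interval", positive = TRUE)
  if (window_frames < 2) stop_config("`window_frames` must be >= 2")
  ord <- order(track$frame)
  frame <- track$frame[ord]
  x <- track$x_um[ord]; y <- track$y_um[ord]
  n <- length(x)
  dt_min <- frame_interval / 60
  lag_target <- max(1L, window_frames %/% 2L)
  zero_row <- function() c(
    displacement = 0, speed = 0, cumulative_length = 0, euclidean_distance = 0,
    directedness = 0, outreach_ratio = 0, msd = 0, max_displacement = 0,
    turn_angle = 0, arrest_coefficient = 0, velocity_x = 0, velocity_y = 0,
    mean_window_speed = 0
  )
  out <- matrix(0, n, 13, dimnames = list(NULL, names(zero_row())))
  complete <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - window_frames + 1L)
    complete[i] <- (i - lo + 1L) == window_frames
    if (i == 1L) next  # leading frame: no step yet, all zeros
    wx <- x[lo:i]; wy <- y[lo:i]
    m <- length(wx)
    steps <- sqrt(diff(wx)^2 + diff(wy)^2)
    len <- sum(steps)
    net <- sqrt((wx[m] - wx[1])^2 + (wy[m] - wy[1])^2)
    exc <- sqrt((wx - wx[1])^2 + (wy - wy[1])^2)
    disp <- sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
    dur_min <- (m - 1) * dt_min
    lag <- min(lag_target, m - 1L)
    idx <- seq_len(m - lag)
    msd <- mean((wx[idx + lag] - wx[idx])^2 + (wy[idx + lag] - wy[idx])^2)
    turn <- 0
    if (i >= 3L) {
      v1 <- c(x[i - 1] - x[i - 2], y[i - 1] - y[i - 2])
      v2 <- c(x[i] - x[i - 1], y[i] - y[i - 1])
      n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
      if (n1 > 0 && n2 > 0) {
        turn <- acos(pmin(1, pmax(-1, sum(v1 * v2) / (n1 * n2))))
      }
    }
    out[i, ] <- c(
      displacement = disp,
      speed = disp / dt_min,
      cumulative_length = len,
      euclidean_distance = net,
      directedness = if (len > 0) net / len else 0,
      outreach_ratio = if (len > 0) max(exc) / len else 0,
      msd = msd,
      max_displacement = max(exc),
      turn_angle = turn,
      arrest_coefficient = mean(steps / dt_min < arrest_threshold),
      velocity_x = (wx[m] - wx[1]) / dur_min,
      velocity_y = (wy[m] - wy[1]) / dur_min,
      mean_window_speed = mean(steps) / dt_min
    )
  }
  if (n == 1L) inform("window_kinematics: single-frame track, metrics set to 0")
  res <- as_tibble(as.data.frame(out))
  res$frame <- frame
  res$window_complete <- complete
  res
}

#' Spatial neighbourhood density metrics for one frame
#'
#' For each cell in a frame: a Ripley's K-style statistic -- the number of
#' other centroids within `radius_um`, divided by the global intensity
#' `lambda = N / area` of the frame's bounding region (no edge correction) --
#' and the nearest-neighbour distance. A cell alone in its frame gets K = 0
#' and the bounding-region diagonal (or `radius_um` if that is zero) as a
#' nearest-neighbour sentinel.
#'
#' @param positions data frame with `x_um`, `y_um` for every cell observed in
#'   one frame.
#' @param radius_um neighbourhood radius (> 0).
#' @return a tibble with `ripley_k` and `nn_distance`, one row per input row.
#' @export
spatial_density <- function(positions, radius_um = 50) {
  assert_scalar_number(radius_um, "radius_um", positive = TRUE)
  x <- positions$x_um; y <- positions$y_um
  n <- length(x)
  if (n == 0) return(tibble(ripley_k = double(), nn_distance = double()))
  span_x <- diff(range(x)); span_y <- diff(range(y))
  diag <- sqrt(span_x^2 + span_y^2)
  sentinel <- if (diag > 0) diag else radius_um
  if (n == 1) return(tibble(ripley_k = 0, nn_distance = sentinel))
  d <- as.matrix(stats::dist(cbind(x, y)))
  diag(d) <- Inf
  nn <- apply(d, 1, min)
  counts <- rowSums(d <= radius_um)
  area <- span_x * span_y
  lambda <- if (area > 0) n / area else NA_real_
  k <- if (is.finite(lambda) && lambda > 0) counts / lambda else counts * 0
  tibble(ripley_k = as.numeric(k), nn_distance = as.numeric(nn))
}

#' Compute the full feature table for a track table
#'
#' One row per surviving cell per timepoint carrying all 28 catalogue metrics
#' plus identifiers, `t_seconds` and the `window_complete` flag. Metrics
#' listed in `excluded_features` are still computed and exported; they are
#' only withheld from clustering by [scale_features()].
#'
#' @param tracks a debris-filtered [track_table] tibble.
#' @param config an [experiment_config()]; individual parameters can be
#'   overridden via the remaining arguments.
#' @param window_frames,frame_interval,arrest_threshold,ripley_radius see
#'   [window_kinematics()] and [spatial_density()].
#' @return a `feature_table` tibble with attributes `catalogue` and
#'   `window_frames`.
#' @export
compute_features <- function(tracks, config = NULL,
                             window_frames = NULL, frame_interval = NULL,
                             arrest_threshold = NULL, ripley_radius = NULL) {
  window_frames <- window_frames %||% config$window_frames %||% 8L
  frame_interval <- frame_interval %||% config$frame_interval %||% 40
  arrest_threshold <- arrest_threshold %||% config$arrest_threshold_um_min %||% 2
  ripley_radius <- ripley_radius %||% config$ripley_radius_um %||% 50
  tracks <- new_track_table(tracks, validate = FALSE)
  if (nrow(tracks) == 0) stop_data("cannot compute features of an empty track table")

  morph <- tryCatch(
    t(vapply(tracks$contour, contour_morphology, numeric(13))),
    error = function(e) stop_data(sprintf("morphology failed: %s", conditionMessage(e)))
  )

  kin <- tracks |>
    group_by(.data$track_uid) |>
    dplyr::group_modify(~ window_kinematics(.x, window_frames, frame_interval,
                                            arrest_threshold)) |>
    ungroup() |>
    arrange(.data$track_uid, .data$frame)

  spat <- tracks |>
    group_by(.data$frame) |>
    dplyr::group_modify(~ dplyr::bind_cols(
      select(.x, "track_uid"),
      spatial_density(.x, ripley_radius)
    )) |>
    ungroup()

  base <- tracks |>
    select("condition", "replicate", "track_uid", "frame", "x_um", "y_um") |>
    mutate(t_seconds = .data$frame * frame_interval)

  out <- dplyr::bind_cols(base, as_tibble(as.data.frame(morph))) |>
    left_join(kin, by = c("track_uid", "frame")) |>
    left_join(spat, by = c("track_uid", "frame")) |>
    arrange(.data$track_uid, .data$frame)

  cat <- metric_catalogue()
  stopifnot(all(cat$name %in% names(out)))
  if (anyNA(out[cat$name])) stop_data("internal error: missing metric values")
  attr(out, "catalogue") <- cat
  attr(out, "window_frames") <- window_frames
  class(out) <- c("feature_table", class(out))
  out
}

#' Export a feature table (CSV) and its catalogue (JSON)
#' @param features a `feature_table` from [compute_features()].
#' @param path CSV output path; the catalogue goes to `<path>.catalogue.json`.
#' @return `path`, invisibly.
#' @export
export_features <- function(features, path) {
  write.csv(as.data.frame(features), path, row.names = FALSE)
  cat <- attr(features, "catalogue") %||% metric_catalogue()
  jsonlite::write_json(cat, paste0(path, ".catalogue.json"), dataframe = "rows")
  invisible(path)
}
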