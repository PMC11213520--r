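#' Motion/shape regime specifications for the track simulator
#'
#' A regime couples a motion model with an elliptical shape model. Motion
#' models: `stationary` (isotropic jitter only), `brownian` (2D diffusion
#' with coefficient `diffusion` in um^2/min; per-step displacement sd
#' `sqrt(2 * D * dt)` per axis), `persistent` (persistent random walk: each
#' step keeps the previous heading plus angular noise with
#' `sd = pi * (1 - persistence)`, so `persistence = 1` walks a straight
#' line), `oscillatory` (alternating run/pause blocks of `run_frames` /
#' `pause_frames`). Contours are ellipses with lognormal-ish axis jitter;
#' with `align = "aligned"` the major axis follows the instantaneous
#' velocity (uniform orientation when at rest).
#'
#' These regimes emulate the migratory phenotypes reported for primary
#' immune cells on integrin ligands: stationary/quiescent cells, fast
#' persistent crawlers and oscillatory "stop and go" confined migration.
#'
#' @param name regime label used in ground truth.
#' @param motion one of `"stationary"`, `"brownian"`, `"persistent"`,
#'   `"oscillatory"`.
#' @param speed mean speed in um/min (persistent/oscillatory runs).
#' @param persistence directional persistence in `[0, 1]`.
#' @param diffusion diffusion coefficient `D` in um^2/min (brownian).
#' @param run_frames,pause_frames oscillatory block lengths (frames).
#' @param jitter positional jitter sd (um/frame) for stationary cells.
#' @param axes ellipse semi-axes `c(a, b)` in um.
#' @param axis_noise relative sd of per-frame axis jitter.
#' @param align `"aligned"` (major axis along velocity) or `"none"`.
#' @return a `regime` object.
#' @export
regime <- function(name,
                   motion = c("stationary", "brownian", "persistent", "oscillatory"),
                   speed = 3, persistence = 0.8, diffusion = 1,
                   run_frames = 5L, pause_frames = 5L, jitter = 0.05,
                   axes = c(8, 5), axis_noise = 0.05,
                   align = c("aligned", "none")) {
  motion <- match.arg(motion)
  align <- match.arg(align)
  if (speed < 0) stop_config("`speed` must be >= 0")
  if (persistence < 0 || persistence > 1) stop_config("`persistence` must be in [0, 1]")
  if (diffusion < 0) stop_config("`diffusion` must be >= 0")
  if (any(axes <= 0)) stop_config("`axes` must be > 0")
  structure(list(
    name = name, motion = motion, speed = speed, persistence = persistence,
    diffusion = diffusion, run_frames = as.integer(run_frames),
    pause_frames = as.integer(pause_frames), jitter = jitter,
    axes = sort(as.numeric(axes), decreasing = TRUE), axis_noise = axis_noise,
    align = align
  ), class = "regime")
}

#' @rdname regime
#' @export
regime_stationary <- function(name = "stationary", axes = c(6.3, 6.3), ...) {
  regime(name, motion = "stationary", axes = axes, ...)
}

#' @rdname regime
#' @param ... passed on to [regime()].
#' @export
regime_brownian <- function(name = "brownian", diffusion = 1, ...) {
  regime(name, motion = "brownian", diffusion = diffusion, ...)
}

#' @rdname regime
#' @export
regime_persistent <- function(name = "persistent", speed = 4, persistence = 0.9,
                              axes = c(10, 4), ...) {
  regime(name, motion = "persistent", speed = speed, persistence = persistence,
         axes = axes, ...)
}

#' @rdname regime
#' @export
regime_oscillatory <- function(name = "oscillatory", speed = 4, run_frames = 5L,
                               pause_frames = 5L, axes = c(8, 5), ...) {
  regime(name, motion = "oscillatory", speed = speed, run_frames = run_frames,
         pause_frames = pause_frames, axes = axes, ...)
}

#' Simulate one track under a regime
#'
#' Positions are in um; draws come from the current RNG stream (seed it, or
#' pass `seed`, for reproducibility). The per-frame ground-truth regime label
#' is attached (for oscillatory regimes, runs are labelled
#' `"<name>:run"` / `"<name>:pause"`).
#'
#' @param regime a [regime()].
#' @param n_frames number of frames (>= 2).
#' @param frame_interval seconds between frames.
#' @param start starting position `c(x, y)` in um.
#' @param seed optional integer seed.
#' @return a tibble: `frame`, `x_um`, `y_um`, `regime`.
#' @export
simulate_track <- function(regime, n_frames, frame_interval = 40,
                           start = c(0, 0), seed = NULL) {
  stopifnot(inherits(regime, "regime"))
  n_frames <- as.integer(n_frames)
  if (n_frames < 2) stop_config("`n_frames` must be >= 2")
  with_local_seed(seed, {
    dt_min <- frame_interval / 60
    step_len <- regime$speed * dt_min
    x <- numeric(n_frames); y <- numeric(n_frames)
    x[1] <- start[1]; y[1] <- start[2]
    label <- rep(regime$name, n_frames)
    heading <- runif(1, 0, 2 * pi)
    moving_state <- function(i) {
      period <- regime$run_frames + regime$pause_frames
      ((i - 2L) %% period) < regime$run_frames
    }
    for (i in 2:n_frames) {
      dx <- 0; dy <- 0
      if (regime$motion == "stationary") {
        dx <- rnorm(1, 0, regime$jitter); dy <- rnorm(1, 0, regime$jitter)
      } else if (regime$motion == "brownian") {
        s <- sqrt(2 * regime$diffusion * dt_min)
        dx <- rnorm(1, 0, s); dy <- rnorm(1, 0, s)
      } else if (regime$motion == "persistent") {
        heading <- heading + rnorm(1, 0, pi * (1 - regime$persistence))
        dx <- step_len * cos(heading); dy <- step_len * sin(heading)
      } else if (regime$motion == "oscillatory") {
        if (moving_state(i)) {
          heading <- heading + rnorm(1, 0, 0.2)
          dx <- step_len * cos(heading); dy <- step_len * sin(heading)
          label[i] <- paste0(regime$name, ":run")
        } else {
          dx <- rnorm(1, 0, regime$jitter); dy <- rnorm(1, 0, regime$jitter)
          label[i] <- paste0(regime$name, ":pause")
        }
      }
      x[i] <- x[i - 1] + dx
      y[i] <- y[i - 1] + dy
    }
    if (regime$motion == "oscillatory") label[1] <- label[2]
    tibble(frame = 0:(n_frames - 1L), x_um = x, y_um = y, regime = label)
  })
}

#' Render an elliptical cell contour
#'
#' A 64-vertex ellipse centred on the cell position; with aligned coupling
#' the major axis follows the velocity vector (uniform orientation when the
#' cell is at rest). Axis jitter is multiplicative Gaussian, truncated to
#' stay positive. The polygon is simple and closed by construction, so
#' morphology metrics have analytic expectations.
#'
#' @param position `c(x, y)` centre in um.
#' @param regime a [regime()] providing the shape model.
#' @param velocity `c(vx, vy)` instantaneous velocity (any units; only the
#'   direction is used).
#' @param n_vertices vertices in the polygon.
#' @return a two-column vertex matrix (um).
#' @export
render_contour <- function(position, regime, velocity = c(0, 0), n_vertices = 64L) {
  stopifnot(inherits(regime, "regime"))
  a <- regime$axes[1] * max(0.2, 1 + rnorm(1, 0, regime$axis_noise))
  b <- regime$axes[2] * max(0.2, 1 + rnorm(1, 0, regime$axis_noise))
  speed2 <- sum(velocity^2)
  phi <- if (regime$align == "aligned" && speed2 > 1e-12) {
    atan2(velocity[2], velocity[1])
  } else {
    runif(1, 0, pi)
  }
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  ex <- a * cos(th); ey <- b * sin(th)
  cbind(position[1] + ex * cos(phi) - ey * sin(phi),
        position[2] + ex * sin(phi) + ey * cos(phi))
}

#' Specification of a synthetic multi-condition experiment
#'
#' Each condition is a mixture over regimes; tracks draw their regime from the
#' mixture and their length uniformly from `len_range`. The default experiment
#' is a desk-scale two-condition study (a control dominated by stationary
#' cells and a treated condition enriched for fast persistent and oscillatory
#' migration), 2 replicates x 20 tracks, 40 s frame interval, 0.5 um/px --
#' about 4000--5000 cell-timepoints so the full pipeline runs in minutes.
#'
#' @param conditions named list: for each condition, a list of [regime()]s and
#'   a `proportions` vector summing to 1.
#' @param n_tracks tracks per replicate per condition.
#' @param replicates replicate names.
#' @param len_range inclusive track length range (frames).
#' @param frame_interval seconds per frame.
#' @param pixel_size um per pixel (fixture files are written in pixels).
#' @param field_um square field side (um): starting positions are uniform in
#'   it.
#' @param seed integer seed.
#' @return a `synthetic_experiment_spec` object.
#' @export
synthetic_experiment_spec <- function(conditions = NULL, n_tracks = 20L,
                                      replicates = c("rep1", "rep2"),
                                      len_range = c(45L, 60L),
                                      frame_interval = 40, pixel_size = 0.5,
                                      field_um = 400, seed = 1L) {
  conditions <- conditions %||% list(
    control = list(
      regimes = list(regime_stationary(), regime_persistent(speed = 3),
                     regime_oscillatory(speed = 3)),
      proportions = c(0.5, 0.3, 0.2)
    ),
    treated = list(
      regimes = list(regime_stationary(), regime_persistent(speed = 5),
                     regime_oscillatory(speed = 4)),
      proportions = c(0.2, 0.5, 0.3)
    )
  )
  for (nm in names(conditions)) {
    p <- conditions[[nm]]$proportions
    if (abs(sum(p) - 1) > 1e-8) {
      stop_config(sprintf("mixture proportions of '%s' must sum to 1", nm))
    }
    if (length(p) != length(conditions[[nm]]$regimes)) {
      stop_config(sprintf("'%s': one proportion per regime required", nm))
    }
  }
  structure(list(
    conditions = conditions, n_tracks = as.integer(n_tracks),
    replicates = replicates, len_range = as.integer(len_range),
    frame_interval = frame_interval, pixel_size = pixel_size,
    field_um = field_um, seed = as.integer(seed)
  ), class = "synthetic_experiment_spec")
}

#' Simulate an experiment in memory
#'
#' Generates the full track table (with contours, in um) and the track-level
#' ground truth without touching disk. [simulate_experiment()] writes the
#' same draw to a condition/replicate folder tree.
#'
#' @param spec a [synthetic_experiment_spec()].
#' @return a list: `tracks` ([track_table] tibble), `ground_truth` tibble
#'   (`condition`, `replicate`, `track_uid`, `regime`, per-frame labels in
#'   `frame_regimes` list-column).
#' @export
simulate_tracks <- function(spec) {
  stopifnot(inherits(spec, "synthetic_experiment_spec"))
  with_local_seed(spec$seed, {
    rows <- list(); gt <- list()
    for (cond in names(spec$conditions)) {
      mix <- spec$conditions[[cond]]
      for (rep_ in spec$replicates) {
        for (tid in seq_len(spec$n_tracks)) {
          comp <- sample.int(length(mix$regimes), 1, prob = mix$proportions)
          rg <- mix$regimes[[comp]]
          lens <- spec$len_range[1]:spec$len_range[2]
          n_frames <- lens[sample.int(length(lens), 1)]
          start <- runif(2, 0, spec$field_um)
          tr <- simulate_track(rg, n_frames, spec$frame_interval, start = start)
          vx <- c(0, diff(tr$x_um)); vy <- c(0, diff(tr$y_um))
          contours <- lapply(seq_len(n_frames), function(i) {
            render_contour(c(tr$x_um[i], tr$y_um[i]), rg, c(vx[i], vy[i]))
          })
          uid <- paste(cond, rep_, tid, sep = "/")
          rows[[length(rows) + 1L]] <- tibble(
            condition = cond, replicate = rep_, track_uid = uid,
            frame = tr$frame, x_um = tr$x_um, y_um = tr$y_um, contour = contours
          )
          gt[[length(gt) + 1L]] <- tibble(
            condition = cond, replicate = rep_, track_uid = uid,
            local_id = tid, regime = rg$name, n_frames = n_frames,
            frame_regimes = list(tr$regime)
          )
        }
      }
    }
    list(tracks = new_track_table(bind_rows(rows)), ground_truth = bind_rows(gt))
  })
}

#' Write a synthetic experiment to disk in the package's input formats
#'
#' Creates the two-tier `condition/replicate` folder tree containing one
#' track file per replicate -- the minimal h5 schema read by
#' [read_tracks_h5()] (`format = "h5"`), or the generic CSV dialect
#' (`format = "csv"`) -- plus `ground_truth.csv` per replicate and a ready
#' `config.yaml` at the root so [run_pipeline()] can consume the tree
#' directly. Coordinates are written in pixels (divided by `pixel_size`),
#' exactly as a tracking tool would emit them.
#'
#' @param spec a [synthetic_experiment_spec()].
#' @param dir output directory (the master path).
#' @param format `"h5"` or `"csv"`.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return invisibly, a list with `dir`, `config` (path), `tracks`,
#'   `ground_truth`.
#' @export
simulate_experiment <- function(spec, dir, format = c("h5", "csv"),
                                overwrite = FALSE) {
  format <- match.arg(format)
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite) {
    stop_data(sprintf("output directory '%s' is not empty (use overwrite = TRUE)", dir))
  }
  sim <- simulate_tracks(spec)
  px <- spec$pixel_size
  for (cond in names(spec$conditions)) {
    for (rep_ in spec$replicates) {
      rdir <- file.path(dir, cond, rep_)
      dir.create(rdir, recursive = TRUE, showWarnings = FALSE)
      sub <- filter(sim$tracks, .data$condition == cond, .data$replicate == rep_)
      local_id <- as.integer(sub("^.*/", "", sub$track_uid))
      if (format == "h5") {
        write_tracks_h5(file.path(rdir, "tracks.h5"), sub, local_id, px)
      } else {
        out <- data.frame(
          track_id = local_id, frame = sub$frame,
          x_px = sub$x_um / px, y_px = sub$y_um / px,
          contour_wkt = vapply(sub$contour, function(p) wkt_polygon(p / px),
                               character(1))
        )
        write.csv(out, file.path(rdir, "tracks.csv"), row.names = FALSE)
      }
      gt <- filter(sim$ground_truth, .data$condition == cond,
                   .data$replicate == rep_)
      gt_flat <- tibble(
        track_uid = rep(gt$track_uid, gt$n_frames),
        frame = unlist(lapply(gt$n_frames, function(n) 0:(n - 1L))),
        regime = unlist(gt$frame_regimes),
        track_regime = rep(gt$regime, gt$n_frames)
      )
      write.csv(gt_flat, file.path(rdir, "ground_truth.csv"), row.names = FALSE)
    }
  }
  cfg <- experiment_config(
    master_path = normalizePath(dir),
    conditions = names(spec$conditions),
    pixel_size = px,
    frame_interval = spec$frame_interval,
    min_track_frames = 8L,
    # hyperparameters sized for a desk-scale experiment (a few thousand
    # timepoints) rather than the full-scale defaults
    umap_neighbors_tp = 25L,
    hdbscan_min_cluster_tp = 100L,
    hdbscan_min_samples_tp = 25L,
    traj_len_min = min(spec$len_range), traj_len_max = max(spec$len_range),
    umap_neighbors_traj = 15L,
    hdbscan_min_cluster_traj = 10L, hdbscan_min_samples_traj = 5L,
    rng_seed = spec$seed
  )
  cfg_path <- file.path(dir, "config.yaml")
  write_experiment_config(cfg, cfg_path)
  invisible(list(dir = dir, config = cfg_path, tracks = sim$tracks,
                 ground_truth = sim$ground_truth))
}

write_tracks_h5 <- function(path, tracks, local_id, pixel_size) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "objects")
  rhdf5::h5createGroup(path, "contours")
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  rhdf5::h5write(as.integer(tracks$frame), path, "objects/t")
  rhdf5::h5write(tracks$x_um / pixel_size, path, "objects/x")
  rhdf5::h5write(tracks$y_um / pixel_size, path, "objects/y")
  rhdf5::h5write(as.integer(local_id), path, "objects/track_id")
  nv <- vapply(tracks$contour, nrow, integer(1))
  rhdf5::h5write(as.integer(c(0L, cumsum(nv))), path, "contours/offsets")
  allv <- do.call(rbind, tracks$contour) / pixel_size
  rhdf5::h5write(allv[, 1], path, "contours/x")
  rhdf5::h5write(allv[, 2], path, "contours/y")
  invisible(path)
}
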