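#' Track tables
#'
#' The central input container is a tidy "track table": one row per cell per
#' frame with columns `condition`, `replicate`, `track_uid`, `frame`, `x_um`,
#' `y_um` and a `contour` list-column of two-column vertex matrices (microns,
#' image coordinates with y pointing down). `track_uid` is the namespaced
#' string `"{condition}/{replicate}/{local_id}"` so identical local track ids
#' from different replicates never collide. All geometry is converted from
#' pixels to microns at load time.
#'
#' @name track_table
NULL

new_track_table <- function(df, validate = TRUE) {
  df <- as_tibble(df)
  needed <- c("condition", "replicate", "track_uid", "frame", "x_um", "y_um", "contour")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_format(sprintf("track table is missing column(s): %s",
                        paste(missing, collapse = ", ")))
  }
  df <- arrange(df, .data$track_uid, .data$frame)
  if (validate && nrow(df)) {
    key <- paste(df$track_uid, df$frame)
    if (anyDuplicated(key)) {
      dup <- key[duplicated(key)][1]
      stop_data(sprintf("duplicate (track_uid, frame) observation: %s", dup))
    }
  }
  df
}

#' Read one replicate of tracked segmentations from an h5 file
#'
#' The reader targets a minimal btrack-style layout, which the package's own
#' fixture writer ([simulate_experiment()]) also emits:
#' \describe{
#'   \item{/objects/t, /objects/x, /objects/y}{per-object frame index and
#'     centroid in pixels}
#'   \item{/objects/track_id}{track assignment per object; negative = untracked}
#'   \item{/contours/offsets}{0-based start index per object into the vertex
#'     arrays, length n_objects + 1}
#'   \item{/contours/x, /contours/y}{concatenated contour vertices in pixels}
#' }
#' Objects without a track assignment are dropped and counted in the load
#' report attached as the `"load_report"` attribute.
#'
#' @param path h5 file.
#' @param condition,replicate labels stamped onto every observation.
#' @param pixel_size microns per pixel.
#' @return a [track_table] tibble.
#' @export
read_tracks_h5 <- function(path, condition, replicate, pixel_size) {
  assert_scalar_number(pixel_size, "pixel_size", positive = TRUE)
  if (!file.exists(path)) stop_format(sprintf("h5 file '%s' does not exist", path))
  contents <- tryCatch(rhdf5::h5ls(path), error = function(e) {
    stop_format(sprintf("cannot read h5 file '%s': %s", path, conditionMessage(e)))
  })
  present <- file.path(contents$group, contents$name)
  need <- c("/objects/t", "/objects/x", "/objects/y", "/objects/track_id",
            "/contours/offsets", "/contours/x", "/contours/y")
  absent <- setdiff(need, present)
  if (length(absent)) {
    stop_format(sprintf("h5 file '%s' is missing dataset(s): %s",
                        path, paste(absent, collapse = ", ")))
  }
  h5 <- function(name) as.vector(rhdf5::h5read(path, name))
  t_ <- as.integer(h5("/objects/t"))
  x <- h5("/objects/x"); y <- h5("/objects/y")
  track_id <- as.integer(h5("/objects/track_id"))
  off <- as.integer(h5("/contours/offsets"))
  cx <- h5("/contours/x"); cy <- h5("/contours/y")
  n <- length(t_)
  if (length(off) != n + 1L) {
    stop_format("h5 dataset /contours/offsets must have length n_objects + 1")
  }
  keep <- track_id >= 0L
  dropped <- sum(!keep)
  contours <- lapply(which(keep), function(i) {
    idx <- (off[i] + 1L):off[i + 1L]
    validate_contour(cbind(cx[idx], cy[idx]) * pixel_size)
  })
  out <- new_track_table(tibble(
    condition = condition,
    replicate = replicate,
    track_uid = paste(condition, replicate, track_id[keep], sep = "/"),
    frame = t_[keep],
    x_um = x[keep] * pixel_size,
    y_um = y[keep] * pixel_size,
    contour = contours
  ))
  attr(out, "load_report") <- list(file = path, n_objects = n, dropped = dropped)
  out
}

csv_dialects <- list(
  generic   = c(track_id = "track_id", frame = "frame", x = "x_px", y = "y_px",
                contour = "contour_wkt"),
  trackmate = c(track_id = "TRACK_ID", frame = "FRAME", x = "POSITION_X",
                y = "POSITION_Y", contour = "ROI"),
  usiigaci  = c(track_id = "id", frame = "frame", x = "x", y = "y",
                contour = "contour_wkt")
)

#' Read one replicate of tracked segmentations from a CSV file
#'
#' Supported dialects and their column mappings (all coordinates in pixels):
#' \describe{
#'   \item{generic}{`track_id, frame, x_px, y_px, contour_wkt` (WKT POLYGON).}
#'   \item{trackmate}{TrackMate spot export: `TRACK_ID, FRAME, POSITION_X,
#'     POSITION_Y, ROI`; the three auxiliary header rows below the column names
#'     are skipped; `ROI` is the space-separated `x1 y1 x2 y2 ...` vertex list
#'     relative to the spot centre.}
#'   \item{usiigaci}{`id, frame, x, y, contour_wkt`.}
#' }
#'
#' @inheritParams read_tracks_h5
#' @param dialect one of `"generic"`, `"trackmate"`, `"usiigaci"`.
#' @return a [track_table] tibble (possibly empty, with a warning).
#' @export
read_tracks_csv <- function(path, dialect = c("generic", "trackmate", "usiigaci"),
                            condition, replicate, pixel_size) {
  dialect <- match.arg(dialect)
  assert_scalar_number(pixel_size, "pixel_size", positive = TRUE)
  if (!file.exists(path)) stop_format(sprintf("csv file '%s' does not exist", path))
  map <- csv_dialects[[dialect]]
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "trackmate" && nrow(df) >= 1) {
    # TrackMate writes three non-numeric description rows under the header
    aux <- suppressWarnings(is.na(as.numeric(df[[map[["frame"]]]])))
    df <- df[!aux, , drop = FALSE]
  }
  missing <- setdiff(unname(map), names(df))
  if (length(missing)) {
    stop_format(sprintf("csv file '%s' (%s dialect) is missing column(s): %s",
                        path, dialect, paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) {
    warn(sprintf("csv file '%s' contains no observations", path))
    return(new_track_table(tibble(
      condition = character(), replicate = character(), track_uid = character(),
      frame = integer(), x_um = double(), y_um = double(), contour = list()
    )))
  }
  track_id <- as.integer(df[[map[["track_id"]]]])
  frame <- as.integer(df[[map[["frame"]]]])
  key <- paste(track_id, frame)
  if (anyDuplicated(key)) {
    stop_data(sprintf("csv file '%s' has duplicated (track_id, frame): %s",
                      path, key[duplicated(key)][1]))
  }
  x_px <- as.numeric(df[[map[["x"]]]])
  y_px <- as.numeric(df[[map[["y"]]]])
  contours <- if (dialect == "trackmate") {
    lapply(seq_len(nrow(df)), function(i) {
      v <- as.numeric(strsplit(trimws(df[[map[["contour"]]]][i]), "\\s+")[[1]])
      rel <- matrix(v, ncol = 2, byrow = TRUE)
      validate_contour(sweep(rel, 2, c(x_px[i], y_px[i]), "+") * pixel_size)
    })
  } else {
    lapply(df[[map[["contour"]]]], function(s) parse_wkt_polygon(s) * pixel_size)
  }
  new_track_table(tibble(
    condition = condition,
    replicate = replicate,
    track_uid = paste(condition, replicate, track_id, sep = "/"),
    frame = frame,
    x_um = x_px * pixel_size,
    y_um = y_px * pixel_size,
    contour = contours
  ))
}

#' Collate all replicates of all configured conditions into one track table
#'
#' Walks `master_path/{condition}/{replicate}/` reading every `*.h5` and
#' `*.csv` track file found (CSV dialect inferred from the header). Condition
#' folders listed in the configuration must exist and contain at least one
#' parseable file.
#'
#' @param config an [experiment_config()].
#' @return a [track_table] tibble covering the whole experiment, with a
#'   `"load_report"` attribute summarising files read and objects dropped.
#' @export
collate_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  pieces <- list()
  reports <- list()
  for (cond in config$conditions) {
    cdir <- file.path(config$master_path, cond)
    if (!dir.exists(cdir)) {
      stop_data(sprintf("condition folder '%s' is missing under '%s'",
                        cond, config$master_path))
    }
    reps <- sort(list.dirs(cdir, recursive = FALSE, full.names = FALSE))
    files_read <- 0L
    for (rep in reps) {
      rdir <- file.path(cdir, rep)
      for (f in sort(list.files(rdir, pattern = "\\.(h5|csv)$", full.names = TRUE))) {
        if (basename(f) == "ground_truth.csv") next
        tab <- if (grepl("\\.h5$", f)) {
          read_tracks_h5(f, cond, rep, config$pixel_size)
        } else {
          dialect <- infer_csv_dialect(f)
          read_tracks_csv(f, dialect, cond, rep, config$pixel_size)
        }
        files_read <- files_read + 1L
        pieces[[length(pieces) + 1L]] <- tab
        reports[[length(reports) + 1L]] <-
          attr(tab, "load_report") %||% list(file = f, dropped = 0L)
      }
    }
    if (files_read == 0L) {
      stop_data(sprintf("condition '%s' contains no parseable track files", cond))
    }
  }
  out <- new_track_table(bind_rows(pieces))
  attr(out, "load_report") <- reports
  out
}

infer_csv_dialect <- function(path) {
  header <- names(read.csv(path, nrows = 1, check.names = FALSE))
  for (d in names(csv_dialects)) {
    if (all(unname(csv_dialects[[d]]) %in% header)) return(d)
  }
  stop_format(sprintf("cannot infer CSV dialect of '%s' from its header", path))
}

#' Remove debris and broken tracks
#'
#' Drops whole tracks that were observed for fewer than `min_track_frames`
#' frames, then tracks whose *median* per-frame contour area is not strictly
#' greater than `min_area_um2` (so a cell of exactly the threshold area is
#' removed). The per-track median makes membership robust to single-frame
#' segmentation flicker. Counts of removed tracks per reason are attached as
#' the `"filter_report"` attribute (`short` is counted first; a track failing
#' both rules counts once, as `short`).
#'
#' @param tracks a [track_table] tibble.
#' @param min_area_um2 area threshold in um^2 (strict `>` survives).
#' @param min_track_frames minimum number of observed frames.
#' @return the filtered track table with attribute `"filter_report"`, a list
#'   `list(short =, small =, kept =)` of track counts.
#' @export
filter_debris <- function(tracks, min_area_um2 = 50, min_track_frames = 8L) {
  tracks <- new_track_table(tracks, validate = FALSE)
  if (nrow(tracks) == 0) {
    warn("filter_debris: empty track table")
    attr(tracks, "filter_report") <- list(short = 0L, small = 0L, kept = 0L)
    return(tracks)
  }
  per_track <- tracks |>
    group_by(.data$track_uid) |>
    summarise(
      n_frames = n(),
      median_area = median(vapply(.data$contour, polygon_area, numeric(1))),
      .groups = "drop"
    )
  short <- per_track$n_frames < min_track_frames
  small <- !short & per_track$median_area <= min_area_um2
  keep_uid <- per_track$track_uid[!short & !small]
  out <- filter(tracks, .data$track_uid %in% keep_uid)
  if (nrow(out) == 0) warn("filter_debris: no tracks survive the debris filter")
  attr(out, "filter_report") <- list(
    short = sum(short), small = sum(small), kept = length(keep_uid)
  )
  out
}

#' Export a track table as tidy CSV
#'
#' Contours are serialized as WKT POLYGON strings in microns, giving a
#' lossless plain-text round trip via [import_tracks_csv()].
#'
#' @param tracks a [track_table] tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_tracks <- function(tracks, path) {
  df <- tracks
  df$contour_wkt <- vapply(df$contour, wkt_polygon, character(1))
  df$contour <- NULL
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Re-import a track table written by [export_tracks()]
#' @param path CSV path.
#' @return a [track_table] tibble.
#' @export
import_tracks_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$contour <- lapply(df$contour_wkt, parse_wkt_polygon)
  df$contour_wkt <- NULL
  new_track_table(df)
}
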