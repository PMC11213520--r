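#' Run the full analysis pipeline
#'
#' Executes the workflow stages in order -- `load` (collate the folder tree),
#' `filter` (debris filter), `features`, `differences` (plots-of-difference
#' statistics for headline metrics), `cluster` (behavioural clustering),
#' `trajectories` (sequence analysis) and `report` (figures) -- caching every
#' stage's tables under `out_dir` so later stages can be rerun alone against
#' the cached inputs. A run manifest (resolved config, input file checksums,
#' stage timings, package versions, seed) is written before the first stage
#' and finalized after the last.
#'
#' @param config an [experiment_config()] or the path to a YAML config file.
#' @param stages subset of stages to run (in canonical order).
#' @param out_dir output directory; defaults to `<master_path>/results`.
#' @param metrics metric names carried through the differences stage.
#' @param device figure format for the report stage, `"png"` or `"pdf"`.
#' @return invisibly, a list of stage results plus the finalized `manifest`.
#' @export
run_pipeline <- function(config,
                         stages = c("load", "filter", "features", "differences",
                                    "cluster", "trajectories", "report"),
                         out_dir = NULL,
                         metrics = c("speed", "area"),
                         device = c("png", "pdf")) {
  device <- match.arg(device)
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  all_stages <- c("load", "filter", "features", "differences", "cluster",
                  "trajectories", "report")
  stages <- all_stages[all_stages %in% stages]
  if (length(stages) == 0) stop_config("no valid stages requested")
  out_dir <- out_dir %||% file.path(config$master_path, "results")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sdir <- function(s) {
    d <- file.path(out_dir, s)
    dir.create(d, showWarnings = FALSE)
    d
  }

  input_files <- list.files(file.path(config$master_path, config$conditions),
                            recursive = TRUE, full.names = TRUE,
                            pattern = "\\.(h5|csv)$")
  manifest <- list(
    config = unclass(config),
    seed = config$rng_seed,
    inputs = lapply(input_files, function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }),
    versions = list(r = R.version.string,
                    plasticell = as.character(utils::packageVersion("plasticell"))),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list()
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  res <- list()
  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    out <- tryCatch(fun(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = "plasticell_stage_error", parent = e)
    })
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs"))
    )
    inform(sprintf("[plasticell] stage '%s' done (%.1f s)", name,
                   manifest$stages[[name]]$seconds))
    out
  }

  tracks <- NULL
  if ("load" %in% stages) {
    tracks <- run_stage("load", function() {
      tab <- collate_experiment(config)
      export_tracks(tab, file.path(sdir("load"), "tracks.csv"))
      tab
    })
  }
  filtered <- NULL
  if ("filter" %in% stages) {
    filtered <- run_stage("filter", function() {
      tab <- tracks %||% import_tracks_csv(file.path(out_dir, "load", "tracks.csv"))
      f <- filter_debris(tab, config$min_area_um2, config$min_track_frames)
      export_tracks(f, file.path(sdir("filter"), "tracks_filtered.csv"))
      jsonlite::write_json(attr(f, "filter_report"),
                           file.path(out_dir, "filter", "filter_report.json"),
                           auto_unbox = TRUE)
      f
    })
  }
  features <- NULL
  if ("features" %in% stages) {
    features <- run_stage("features", function() {
      tab <- filtered %||%
        import_tracks_csv(file.path(out_dir, "filter", "tracks_filtered.csv"))
      ft <- compute_features(tab, config)
      export_features(ft, file.path(sdir("features"), "features.csv"))
      ft
    })
  }
  read_features_cache <- function() {
    df <- as_tibble(read.csv(file.path(out_dir, "features", "features.csv"),
                             stringsAsFactors = FALSE))
    attr(df, "catalogue") <- metric_catalogue()
    class(df) <- c("feature_table", class(df))
    df
  }
  diffs <- NULL
  if ("differences" %in% stages) {
    diffs <- run_stage("differences", function() {
      ft <- features %||% read_features_cache()
      d <- sdir("differences")
      control <- config$conditions[1]
      out <- list()
      for (mm in metrics) {
        cmp <- compare_conditions(ft, mm, control = control,
                                  n_boot = config$n_boot,
                                  seed = config$rng_seed)
        write.csv(as.data.frame(cmp),
                  file.path(d, sprintf("effect_size_%s.csv", mm)),
                  row.names = FALSE)
        tp <- timeplot_difference(ft, mm, control = control,
                                  n_boot = min(config$n_boot, 200L),
                                  seed = config$rng_seed)
        write.csv(as.data.frame(tp),
                  file.path(d, sprintf("timeplot_%s.csv", mm)),
                  row.names = FALSE)
        out[[mm]] <- list(effect = cmp, timeplot = tp)
      }
      out
    })
  }
  clusters <- NULL
  if ("cluster" %in% stages) {
    clusters <- run_stage("cluster", function() {
      ft <- features %||% read_features_cache()
      cl <- cluster_behaviours(ft, config)
      d <- sdir("cluster")
      write.csv(as.data.frame(cl$assignments),
                file.path(d, "assignments.csv"), row.names = FALSE)
      write.csv(as.data.frame(cl$fingerprint),
                file.path(d, "fingerprint.csv"), row.names = FALSE)
      write.csv(as.data.frame(top_contributing_metrics(cl)),
                file.path(d, "top_metrics.csv"), row.names = FALSE)
      ex <- split(
        lapply(seq_len(nrow(cl$exemplars)), function(i) {
          list(track_uid = cl$exemplars$track_uid[i], frame = cl$exemplars$frame[i])
        }),
        cl$exemplars$cluster_id
      )
      jsonlite::write_json(
        list(silhouette = unclass(cl$silhouette), exemplars = ex),
        file.path(d, "cluster_summary.json"), auto_unbox = TRUE, digits = NA)
      cl
    })
  }
  trajectories <- NULL
  if ("trajectories" %in% stages) {
    trajectories <- run_stage("trajectories", function() {
      cl <- clusters
      asn <- if (!is.null(cl)) cl$assignments else {
        as_tibble(read.csv(file.path(out_dir, "cluster", "assignments.csv"),
                           stringsAsFactors = FALSE))
      }
      seqs <- behaviour_sequences(asn)
      seqs_f <- filter_sequences(seqs, config$traj_len_min, config$traj_len_max)
      tr <- cluster_trajectories(
        seqs_f,
        n_neighbors = config$umap_neighbors_traj,
        min_cluster_size = config$hdbscan_min_cluster_traj,
        min_samples = config$hdbscan_min_samples_traj,
        seed = config$rng_seed
      )
      d <- sdir("trajectories")
      export_sequences(seqs_f, file.path(d, "sequences.csv"))
      write.csv(as.data.frame(tr$assignments),
                file.path(d, "assignments.csv"), row.names = FALSE)
      write.csv(tr$distances, file.path(d, "distance_matrix.csv"))
      fp <- trajectory_fingerprints(tr)
      write.csv(as.data.frame(fp$by_condition),
                file.path(d, "fingerprint_by_condition.csv"), row.names = FALSE)
      write.csv(as.data.frame(fp$composition),
                file.path(d, "fingerprint_composition.csv"), row.names = FALSE)
      pl <- compare_plasticity(tr, by = "trajectory")
      write.csv(as.data.frame(pl$summary),
                file.path(d, "plasticity_by_trajectory.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(silhouette = unclass(tr$silhouette),
             exemplars = as.data.frame(tr$exemplars)),
        file.path(d, "trajectory_summary.json"), auto_unbox = TRUE, digits = NA)
      tr
    })
  }
  if ("report" %in% stages) {
    run_stage("report", function() {
      d <- sdir("report")
      save_plot <- function(p, name) {
        path <- file.path(d, paste0(name, ".", device))
        ggplot2::ggsave(path, p, width = 7, height = 5, dpi = 150)
        path
      }
      written <- character()
      if (!is.null(diffs)) {
        for (mm in names(diffs)) {
          es <- attr(diffs[[mm]]$effect, "effect_sizes")
          if (length(es)) {
            written <- c(written, save_plot(autoplot(es[[1]]),
                                            paste0("effect_size_", mm)))
          }
          written <- c(written, save_plot(autoplot(diffs[[mm]]$timeplot),
                                          paste0("timeplot_", mm)))
        }
      }
      if (!is.null(clusters)) {
        written <- c(written, save_plot(autoplot(clusters), "umap_clusters"))
        if (!is.null(clusters$fingerprint)) {
          written <- c(written, save_plot(autoplot(clusters$fingerprint),
                                          "fingerprint_behaviour"))
        }
      }
      if (!is.null(trajectories)) {
        written <- c(written, save_plot(autoplot(trajectories), "umap_trajectories"))
        fp <- trajectory_fingerprints(trajectories)
        written <- c(written, save_plot(autoplot(fp$by_condition),
                                        "fingerprint_trajectory"))
      }
      written
    })
  }

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  invisible(list(
    tracks = tracks, filtered = filtered, features = features,
    differences = diffs, clusters = clusters, trajectories = trajectories,
    manifest = manifest, out_dir = out_dir
  ))
}
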