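#' Standardize the feature table for clustering
#'
#' Z-scores each included metric (or median/IQR with `method = "robust"`).
#' Metrics on the exclusion list and zero-variance columns (dropped with a
#' warning) do not enter the clustering space; the location/scale of every
#' kept column is stored for the inverse transform.
#'
#' @param features a `feature_table` from [compute_features()].
#' @param excluded_features metric names to withhold from clustering
#'   (defaults to turn angle and Ripley's K).
#' @param method `"zscore"` or `"robust"` (median/IQR).
#' @return a `scaled_features` object: `matrix` (records x metrics), `center`,
#'   `scale`, `metrics`, `dropped`, and `index` (identifier columns aligned to
#'   the matrix rows).
#' @export
scale_features <- function(features, excluded_features = c("turn_angle", "ripley_k"),
                           method = c("zscore", "robust")) {
  method <- match.arg(method)
  if (nrow(features) < 2) stop_data("scale_features needs >= 2 records")
  cat <- attr(features, "catalogue") %||% metric_catalogue()
  bad <- setdiff(excluded_features, cat$name)
  if (length(bad)) {
    stop_config(sprintf("excluded_features not in the catalogue: %s",
                        paste(bad, collapse = ", ")))
  }
  keep <- setdiff(cat$name, excluded_features)
  m <- as.matrix(as.data.frame(features)[, keep, drop = FALSE])
  center <- if (method == "zscore") apply(m, 2, mean) else apply(m, 2, median)
  scale_ <- if (method == "zscore") apply(m, 2, sd) else apply(m, 2, stats::IQR)
  zero <- !is.finite(scale_) | scale_ <= 0
  if (all(zero)) stop_data("all feature columns have zero variance")
  if (any(zero)) {
    warn(sprintf("dropping zero-variance metric(s): %s",
                 paste(keep[zero], collapse = ", ")))
  }
  keep <- keep[!zero]
  z <- sweep(sweep(m[, keep, drop = FALSE], 2, center[keep]), 2, scale_[keep], "/")
  idx_cols <- intersect(c("condition", "replicate", "track_uid", "frame"),
                        names(features))
  structure(list(
    matrix = z,
    center = center[keep], scale = scale_[keep],
    metrics = keep,
    dropped = setdiff(names(zero)[zero], character()),
    method = method,
    index = as_tibble(features)[, idx_cols]
  ), class = "scaled_features")
}

#' UMAP embedding of scaled features
#'
#' Three components by default (behavioural space is plotted and clustered as
#' UMAP 1--3). Runs single-threaded with a fixed seed so repeated calls are
#' bit-identical. For trajectory analysis, pass a precomputed `dist` object
#' instead of a feature matrix.
#'
#' @param x a `scaled_features` object, a numeric matrix, or a `dist`.
#' @param n_neighbors UMAP nearest-neighbour count.
#' @param n_components embedding dimensionality (3 per-timepoint, 2 for
#'   trajectories).
#' @param seed integer seed.
#' @param ... further arguments to [uwot::umap()].
#' @return numeric matrix (records x `n_components`), columns `umap1..`.
#' @export
embed_umap <- function(x, n_neighbors = 50L, n_components = 3L, seed = 1L, ...) {
  m <- if (inherits(x, "scaled_features")) x$matrix else x
  n <- if (inherits(m, "dist")) attr(m, "Size") else nrow(m)
  if (n < n_neighbors + 1) {
    stop_data(sprintf(
      "embed_umap: %d records for n_neighbors = %d; reduce n_neighbors below %d",
      n, n_neighbors, n))
  }
  emb <- with_local_seed(seed, uwot::umap(
    m, n_neighbors = n_neighbors, n_components = n_components,
    n_threads = 1, n_sgd_threads = 0, batch = FALSE, ...
  ))
  colnames(emb) <- paste0("umap", seq_len(ncol(emb)))
  emb
}

#' Mean silhouette score of a clustering
#'
#' Computed in the clustering space over clustered points only (noise
#' excluded), optionally on a seeded subsample for large datasets. Ranges
#' -1..1; high scores mean points sit well inside their own cluster. With
#' fewer than two clusters the score is not computable and `NA` is returned
#' with a `reason` attribute.
#'
#' @param points matrix of points in the clustering space.
#' @param labels integer labels (-1 = noise).
#' @param subsample maximum number of clustered points used.
#' @param seed seed for the subsample.
#' @return mean silhouette width (scalar), or `NA` when undefined.
#' @export
silhouette_of_clustering <- function(points, labels, subsample = 5000L, seed = 1L) {
  points <- as.matrix(points)
  keep <- which(labels >= 0)
  if (length(unique(labels[keep])) < 2) {
    return(structure(NA_real_, reason = "fewer than 2 clusters: silhouette not computable"))
  }
  if (length(keep) > subsample) {
    keep <- with_local_seed(seed, sort(sample(keep, subsample)))
    if (length(unique(labels[keep])) < 2) {
      return(structure(NA_real_, reason = "subsample collapsed to one cluster"))
    }
  }
  sil <- cluster::silhouette(labels[keep], stats::dist(points[keep, , drop = FALSE]))
  mean(sil[, "sil_width"])
}

#' Behavioural clustering of the feature table
#'
#' The per-timepoint clustering stage: scale features, embed with UMAP,
#' cluster the embedding (or the full-dimensional scaled matrix with
#' `space = "ndim"`) with [hdbscan()], score with a silhouette, and extract
#' density-central exemplars. Every record receives a behavioural cluster ID
#' (`-1` = unclustered).
#'
#' @param features a `feature_table`.
#' @param config optional [experiment_config()] supplying defaults.
#' @param excluded_features metrics withheld from clustering.
#' @param n_neighbors,n_components UMAP parameters.
#' @param min_cluster_size,min_samples HDBSCAN parameters.
#' @param space cluster the `"embedding"` (default) or the `"ndim"` scaled
#'   feature matrix.
#' @param seed integer seed for the whole stage.
#' @param k_exemplars exemplars kept per cluster.
#' @param allow_single_cluster passed to [hdbscan()].
#' @return a `behaviour_clusters` object: `assignments` tibble (identifiers,
#'   `umap1..3`, `cluster_id`, `lambda`), `scaled`, `silhouette`, `exemplars`,
#'   `fingerprint` (per condition), `model` and `parameters`.
#' @export
cluster_behaviours <- function(features, config = NULL,
                               excluded_features = NULL,
                               n_neighbors = NULL, n_components = 3L,
                               min_cluster_size = NULL, min_samples = NULL,
                               space = c("embedding", "ndim"),
                               seed = NULL, k_exemplars = 5L,
                               allow_single_cluster = FALSE) {
  space <- match.arg(space)
  excluded_features <- excluded_features %||% config$excluded_features %||%
    c("turn_angle", "ripley_k")
  n_neighbors <- n_neighbors %||% config$umap_neighbors_tp %||% 50L
  min_cluster_size <- min_cluster_size %||% config$hdbscan_min_cluster_tp %||% 500L
  min_samples <- min_samples %||% config$hdbscan_min_samples_tp %||% 300L
  seed <- seed %||% config$rng_seed %||% 1L

  scaled <- scale_features(features, excluded_features)
  emb <- embed_umap(scaled, n_neighbors = n_neighbors,
                    n_components = n_components, seed = seed)
  pts <- if (space == "embedding") emb else scaled$matrix
  model <- hdbscan(pts, min_cluster_size = min_cluster_size,
                   min_samples = min_samples,
                   allow_single_cluster = allow_single_cluster)
  sil <- silhouette_of_clustering(pts, model$labels, seed = seed)
  assignments <- dplyr::bind_cols(
    scaled$index,
    as_tibble(as.data.frame(emb)),
    tibble(cluster_id = model$labels, lambda = model$lambda)
  )
  out <- structure(list(
    assignments = assignments,
    scaled = scaled,
    model = model,
    silhouette = sil,
    clustering_space = space,
    parameters = list(
      excluded_features = excluded_features, n_neighbors = n_neighbors,
      n_components = n_components, min_cluster_size = min_cluster_size,
      min_samples = min_samples, seed = seed,
      allow_single_cluster = allow_single_cluster
    )
  ), class = "behaviour_clusters")
  out$exemplars <- extract_exemplars(out, k = k_exemplars)
  out$fingerprint <- if ("condition" %in% names(assignments)) {
    cluster_fingerprint(model$labels, assignments$condition)
  }
  out
}

#' @exportS3Method base::print
print.behaviour_clusters <- function(x, ...) {
  cat(sprintf("<behaviour_clusters> %d records -> %d cluster(s) + %d unclustered\n",
              nrow(x$assignments), x$model$n_clusters, x$model$n_noise))
  cat(sprintf("  space: %s; silhouette: %s\n", x$clustering_space,
              ifelse(is.na(x$silhouette), "not computable",
                     sprintf("%.3f", x$silhouette))))
  invisible(x)
}

#' Density-central exemplar records per behavioural cluster
#'
#' For each cluster, the `k` members with the highest cluster-persistence
#' lambda (the most density-central points, the last to detach from the
#' cluster in the density hierarchy), mapped back to `(track_uid, frame)` so
#' contours and tracks can be rendered. Ties are broken by stable record
#' order. Clusters smaller than `k` return all members.
#'
#' @param clusters a `behaviour_clusters` object.
#' @param k exemplars per cluster.
#' @return a tibble: `cluster_id`, `rank`, identifier columns, `lambda`.
#' @export
extract_exemplars <- function(clusters, k = 5L) {
  a <- clusters$assignments
  out <- a |>
    mutate(.row = dplyr::row_number()) |>
    filter(.data$cluster_id >= 0) |>
    group_by(.data$cluster_id) |>
    arrange(dplyr::desc(.data$lambda), .data$.row, .by_group = TRUE) |>
    dplyr::slice_head(n = k) |>
    mutate(rank = dplyr::row_number()) |>
    ungroup() |>
    select(-".row")
  out
}

#' Metrics that most distinguish each cluster
#'
#' For every cluster, metrics ranked by the absolute difference between the
#' cluster's median scaled value and the median scaled value of all other
#' records ("maximal variation from the rest"), with the cluster's scaled
#' median reported alongside. Noise records are excluded.
#'
#' @param clusters a `behaviour_clusters` object (or a `scaled_features`
#'   object together with `labels`).
#' @param k metrics reported per cluster (clipped to the catalogue size).
#' @param labels optional label vector when `clusters` is `scaled_features`.
#' @return a tibble: `cluster_id`, `rank`, `metric`, `scaled_median`, `score`.
#' @export
top_contributing_metrics <- function(clusters, k = 3L, labels = NULL) {
  if (inherits(clusters, "behaviour_clusters")) {
    z <- clusters$scaled$matrix
    labels <- clusters$model$labels
  } else if (inherits(clusters, "scaled_features")) {
    z <- clusters$matrix
    if (is.null(labels)) stop_data("supply `labels` with scaled features")
  } else {
    stop_data("unsupported input to top_contributing_metrics")
  }
  ids <- sort(unique(labels[labels >= 0]))
  k <- min(k, ncol(z))
  bind_rows(lapply(ids, function(cid) {
    inside <- labels == cid
    med_in <- apply(z[inside, , drop = FALSE], 2, median)
    med_out <- apply(z[!inside, , drop = FALSE], 2, median)
    score <- abs(med_in - med_out)
    ord <- order(score, decreasing = TRUE)[seq_len(k)]
    tibble(cluster_id = cid, rank = seq_len(k),
           metric = colnames(z)[ord],
           scaled_median = unname(med_in[ord]),
           score = unname(score[ord]))
  }))
}

#' Behavioural fingerprint: percentage of records per cluster per group
#'
#' Row-normalized composition table; each row (condition, or trajectory ID)
#' sums to 100%. Unclustered records appear as their own `unclustered` column
#' and are included in the 100%.
#'
#' @param labels integer cluster labels (-1 = unclustered).
#' @param groups aligned grouping vector (condition names).
#' @return a `fingerprint` tibble; first column `condition`, one column per
#'   cluster ID.
#' @export
cluster_fingerprint <- function(labels, groups) {
  build_fingerprint(groups, labels, group_name = "condition")
}

#' Per-metric colouring of the embedding ("metric heat maps in UMAP space")
#'
#' Long-format export of the scaled value of each metric at each embedded
#' point, ready for plotting metric intensity over the embedding.
#'
#' @param clusters a `behaviour_clusters` object.
#' @param metrics subset of metric names (default: all clustered metrics).
#' @return a tibble: `record`, `umap1..`, `metric`, `value` (scaled units).
#' @export
metric_heatmap_data <- function(clusters, metrics = NULL) {
  stopifnot(inherits(clusters, "behaviour_clusters"))
  z <- clusters$scaled$matrix
  metrics <- metrics %||% colnames(z)
  bad <- setdiff(metrics, colnames(z))
  if (length(bad)) stop_data(sprintf("not in the clustered metrics: %s",
                                     paste(bad, collapse = ", ")))
  emb <- clusters$assignments[, grep("^umap", names(clusters$assignments)), drop = FALSE]
  base <- dplyr::bind_cols(tibble(record = seq_len(nrow(emb))), emb)
  bind_rows(lapply(metrics, function(mm) {
    mutate(base, metric = mm, value = unname(z[, mm]))
  }))
}
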