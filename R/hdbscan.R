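#' Hierarchical density-based clustering (HDBSCAN)
#'
#' A full HDBSCAN implementation: core distances from the `min_samples`-th
#' nearest neighbour (counting the point itself), mutual reachability
#' distances, a minimum spanning tree, the condensed cluster hierarchy at
#' `min_cluster_size`, and stability-based excess-of-mass cluster extraction.
#' Labels are integers starting at 0; `-1` marks unclustered (noise) points
#' sitting in low-density regions or between dense regions.
#'
#' Per-point `lambda` values (1 / the mutual-reachability distance at which a
#' point leaves its cluster) quantify how density-central each point is and
#' drive exemplar extraction.
#'
#' @param x numeric matrix of points (rows) in the clustering space.
#' @param min_cluster_size smallest cluster worth keeping (>= 2).
#' @param min_samples smoothing parameter for the density estimate; defaults
#'   to `min_cluster_size`.
#' @param allow_single_cluster if `TRUE` the hierarchy root may itself be
#'   selected, so a dataset forming one uniform blob yields one cluster
#'   instead of all-noise. Default `FALSE`, matching common library
#'   behaviour.
#' @return an `hdbscan` object: `labels` (integer, -1 = noise), `lambda`,
#'   `n_clusters`, `cluster_sizes`, `parameters`.
#' @export
hdbscan <- function(x, min_cluster_size, min_samples = NULL,
                    allow_single_cluster = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop_data("hdbscan: points must be finite")
  if (min_cluster_size < 2) stop_config("`min_cluster_size` must be >= 2")
  min_samples <- as.integer(min_samples %||% min_cluster_size)
  n <- nrow(x)
  if (n < 2) stop_data("hdbscan needs at least 2 points")
  if (min_samples > n) {
    stop_config(sprintf("`min_samples` (%d) exceeds the number of points (%d)",
                        min_samples, n))
  }
  res <- hdbscan_cpp(x, min_samples, as.integer(min_cluster_size),
                     isTRUE(allow_single_cluster))
  labels <- res$labels
  sizes <- if (res$n_clusters > 0) {
    tabulate(labels + 1L, nbins = res$n_clusters)
  } else integer()
  structure(list(
    labels = labels,
    lambda = res$lambda,
    n_clusters = res$n_clusters,
    cluster_sizes = sizes,
    n_noise = sum(labels < 0),
    parameters = list(min_cluster_size = as.integer(min_cluster_size),
                      min_samples = min_samples,
                      allow_single_cluster = isTRUE(allow_single_cluster))
  ), class = "hdbscan")
}

#' @exportS3Method base::print
print.hdbscan <- function(x, ...) {
  cat(sprintf("<hdbscan> %d cluster(s) over %d points (%d noise)\n",
              x$n_clusters, length(x$labels), x$n_noise))
  if (x$n_clusters > 0) {
    cat("  sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  }
  invisible(x)
}
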