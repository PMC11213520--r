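# broom-style tidiers for fitted result objects

#' Tidy a bootstrap effect-size result
#' @param x an `effect_size` object.
#' @param ... ignored.
#' @return a one-row tibble: `statistic`, `control`, `test`, `estimate`,
#'   `conf.low`, `conf.high`, `p.value`.
#' @export
tidy.effect_size <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    control = x$conditions[["control"]],
    test = x$conditions[["test"]],
    estimate = x$estimate,
    conf.low = x$conf.low,
    conf.high = x$conf.high,
    p.value = x$p_value
  )
}

#' @rdname tidy.effect_size
#' @return for `glance`: a one-row tibble with sample sizes, `n_boot`,
#'   confidence level and whether the interval excludes zero.
#' @export
glance.effect_size <- function(x, ...) {
  tibble(
    n_control = x$n[["control"]], n_test = x$n[["test"]],
    n_boot = length(x$boot), conf = x$conf,
    excludes_zero = x$conf.low > 0 || x$conf.high < 0
  )
}

#' Tidy a rank-test report
#' @param x a `rank_test_report` from [rank_tests()].
#' @param ... ignored.
#' @return the pairwise comparison tibble (`group1`, `group2`, `p_raw`,
#'   `p_adj`).
#' @export
tidy.rank_test_report <- function(x, ...) x$pairwise

#' @rdname tidy.rank_test_report
#' @return for `glance`: one row with the Kruskal--Wallis statistic, df,
#'   p-value, group count and degeneracy flag.
#' @export
glance.rank_test_report <- function(x, ...) {
  tibble(
    statistic = x$kruskal$statistic, df = x$kruskal$df,
    p.value = x$kruskal$p_value, n_groups = length(x$n),
    degenerate = x$degenerate
  )
}

#' Tidy behavioural cluster assignments
#' @param x a `behaviour_clusters` object.
#' @param ... ignored.
#' @return the per-record assignment tibble (identifiers, `umap1..`,
#'   `cluster_id`, `lambda`).
#' @export
tidy.behaviour_clusters <- function(x, ...) x$assignments

#' @rdname tidy.behaviour_clusters
#' @return for `glance`: one row with record count, cluster count, noise
#'   fraction and silhouette.
#' @export
glance.behaviour_clusters <- function(x, ...) {
  tibble(
    n_records = nrow(x$assignments),
    n_clusters = x$model$n_clusters,
    frac_unclustered = x$model$n_noise / nrow(x$assignments),
    silhouette = as.numeric(x$silhouette),
    space = x$clustering_space
  )
}

#' Tidy trajectory assignments
#' @param x a `trajectory_clusters` object.
#' @param ... ignored.
#' @return the per-sequence assignment tibble.
#' @export
tidy.trajectory_clusters <- function(x, ...) x$assignments

#' @rdname tidy.trajectory_clusters
#' @return for `glance`: one row with sequence count, trajectory count, noise
#'   fraction and silhouette.
#' @export
glance.trajectory_clusters <- function(x, ...) {
  tibble(
    n_sequences = nrow(x$assignments),
    n_trajectories = x$model$n_clusters,
    frac_unclustered = x$model$n_noise / nrow(x$assignments),
    silhouette = as.numeric(x$silhouette)
  )
}
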