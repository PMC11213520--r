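# ggplot2 graphics for each result type. Cluster colours are keyed by cluster
# ID through a shared discrete scale so the same ID has the same colour in
# every panel of a run.

cluster_palette <- function(ids) {
  ids <- as.character(ids)
  cols <- grDevices::hcl.colors(max(length(setdiff(ids, "unclustered")), 3L),
                                "Dark 3")
  pal <- setNames(cols[seq_along(setdiff(ids, "unclustered"))],
                  setdiff(ids, "unclustered"))
  c(pal, unclustered = "grey70")
}

#' Plot a bootstrap effect-size distribution
#'
#' The bootstrap distribution of the difference statistic with its percentile
#' interval and the zero ("control") line; an interval clear of zero reads as
#' evidence of a real difference.
#'
#' @param object an `effect_size` from [bootstrap_effect_size()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.effect_size <- function(object, ...) {
  df <- tibble(boot = object$boot)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$boot)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4, colour = NA) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$estimate, colour = "steelblue4") +
    ggplot2::geom_vline(xintercept = c(object$conf.low, object$conf.high),
                        colour = "steelblue4", linetype = "dotted") +
    ggplot2::labs(
      x = sprintf("%s(%s) - %s(%s)", object$statistic, object$conditions[["test"]],
                  object$statistic, object$conditions[["control"]]),
      y = "bootstrap density",
      title = sprintf("Effect size: %.3g [%.3g, %.3g]", object$estimate,
                      object$conf.low, object$conf.high)
    ) +
    ggplot2::theme_minimal()
}

#' Plot raw distributions per condition ("plot of difference", left panel)
#'
#' Violin of the metric per condition with median dot and IQR bar.
#'
#' @param features a `feature_table`.
#' @param metric metric column name.
#' @return a ggplot.
#' @export
plot_metric_distribution <- function(features, metric) {
  ggplot2::ggplot(features,
                  ggplot2::aes(x = .data$condition, y = .data[[metric]],
                               fill = .data$condition)) +
    ggplot2::geom_violin(alpha = 0.5, colour = NA, scale = "width") +
    ggplot2::stat_summary(fun = median, geom = "point", size = 2) +
    ggplot2::stat_summary(fun.min = function(v) quantile(v, 0.25),
                          fun.max = function(v) quantile(v, 0.75),
                          geom = "linerange", linewidth = 1.2) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Plot per-timepoint means with confidence ribbons and effect sizes
#'
#' Mean per timepoint per condition (line) with the 95% confidence band;
#' masked frames are left blank.
#'
#' @param object a `timeplot_result` from [timeplot_difference()].
#' @param what `"mean"` for group means, `"effect"` for the per-timepoint
#'   effect size against the control (with zero line).
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.timeplot_result <- function(object, what = c("mean", "effect"), ...) {
  what <- match.arg(what)
  metric <- object$metric[1]
  if (what == "mean") {
    df <- filter(object, !.data$masked)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$mean,
                                     colour = .data$condition,
                                     fill = .data$condition)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                           alpha = 0.2, colour = NA) +
      ggplot2::geom_line() +
      ggplot2::labs(x = "frame", y = sprintf("mean %s", metric)) +
      ggplot2::theme_minimal()
  } else {
    df <- filter(object, !.data$masked, !is.na(.data$effect))
    ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$effect,
                                     colour = .data$condition,
                                     fill = .data$condition)) +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$effect_low,
                                        ymax = .data$effect_high),
                           alpha = 0.2, colour = NA) +
      ggplot2::geom_line() +
      ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
      ggplot2::labs(x = "frame",
                    y = sprintf("effect size on %s vs %s", metric,
                                object$control[1])) +
      ggplot2::theme_minimal()
  }
}

#' Plot a fingerprint table as grouped bars
#'
#' Percentage composition per row group; cluster colours are stable across
#' plots of the same run, with unclustered in grey.
#'
#' @param object a `fingerprint` tibble.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.fingerprint <- function(object, ...) {
  group_col <- names(object)[1]
  long <- tidyr::pivot_longer(as_tibble(object), -all_of(group_col),
                              names_to = "cluster", values_to = "percent")
  long$cluster <- factor(long$cluster, levels = unique(long$cluster))
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[group_col]], y = .data$percent,
                                     fill = .data$cluster)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = cluster_palette(levels(long$cluster))) +
    ggplot2::labs(y = "% of records", x = NULL, fill = "ID") +
    ggplot2::theme_minimal()
}

#' UMAP scatter of behavioural clusters
#' @param object a `behaviour_clusters` object.
#' @param dims which two embedding components to show.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.behaviour_clusters <- function(object, dims = c(1, 2), ...) {
  a <- object$assignments
  a$id <- ifelse(a$cluster_id < 0, "unclustered", as.character(a$cluster_id))
  xc <- paste0("umap", dims[1]); yc <- paste0("umap", dims[2])
  ggplot2::ggplot(a, ggplot2::aes(x = .data[[xc]], y = .data[[yc]],
                                  colour = .data$id)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = cluster_palette(unique(a$id))) +
    ggplot2::labs(colour = "cluster ID") +
    ggplot2::theme_minimal()
}

#' UMAP scatter of trajectory IDs
#' @param object a `trajectory_clusters` object.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.trajectory_clusters <- function(object, ...) {
  a <- object$assignments
  a$id <- ifelse(a$trajectory_id < 0, "unclustered", as.character(a$trajectory_id))
  ggplot2::ggplot(a, ggplot2::aes(x = .data$umap1, y = .data$umap2,
                                  colour = .data$id)) +
    ggplot2::geom_point(size = 1.5, alpha = 0.8) +
    ggplot2::scale_colour_manual(values = cluster_palette(unique(a$id))) +
    ggplot2::labs(colour = "trajectory ID") +
    ggplot2::theme_minimal()
}

#' Exemplar cell graphic: contour and track coloured by cluster ID
#'
#' The de-abstractification view: the cell's contour at the exemplar frame
#' plus its centroid track through time, coloured by behavioural cluster ID,
#' optionally annotated with its top contributing metrics.
#'
#' @param tracks a [track_table] tibble holding the exemplar's track.
#' @param assignments cluster assignments (`track_uid`, `frame`,
#'   `cluster_id`).
#' @param track_uid which track to draw.
#' @param frame contour frame (default: the track's first frame).
#' @param annotate optional tibble from [top_contributing_metrics()] filtered
#'   to this cluster (`metric`, `scaled_median`).
#' @return a ggplot.
#' @export
plot_exemplar_cell <- function(tracks, assignments, track_uid, frame = NULL,
                               annotate = NULL) {
  tr <- filter(tracks, .data$track_uid == !!track_uid)
  if (nrow(tr) == 0) stop_data(sprintf("track '%s' not found", track_uid))
  frame <- frame %||% tr$frame[1]
  asn <- filter(assignments, .data$track_uid == !!track_uid)
  path <- left_join(select(tr, "frame", "x_um", "y_um"),
                    select(asn, "frame", "cluster_id"), by = "frame")
  path$id <- ifelse(is.na(path$cluster_id) | path$cluster_id < 0,
                    "unclustered", as.character(path$cluster_id))
  row <- which(tr$frame == frame)
  p <- ggplot2::ggplot(path, ggplot2::aes(x = .data$x_um, y = .data$y_um)) +
    ggplot2::geom_path(colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$id), size = 1.2) +
    ggplot2::scale_colour_manual(values = cluster_palette(unique(path$id))) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", colour = "cluster ID",
                  title = track_uid) +
    ggplot2::theme_minimal()
  if (length(row) == 1) {
    ct <- as.data.frame(tr$contour[[row]])
    names(ct) <- c("x_um", "y_um")
    ct <- rbind(ct, ct[1, ])
    p <- p + ggplot2::geom_path(data = ct, colour = "black")
  } else {
    warn(sprintf("no contour at frame %d for '%s'; track-only rendering",
                 frame, track_uid))
  }
  if (!is.null(annotate) && nrow(annotate)) {
    lab <- paste(sprintf("%s (%.2f)", annotate$metric, annotate$scaled_median),
                 collapse = "\n")
    p <- p + ggplot2::labs(subtitle = lab)
  }
  p
}

#' Step trace of behavioural cluster ID over time for one track
#'
#' The square-wave "cluster ID versus time" panel shown under each trajectory
#' exemplar: a stationary cell draws a flat line, an alternating one a
#' square wave.
#'
#' @param assignments cluster assignments (`track_uid`, `frame`,
#'   `cluster_id`).
#' @param track_uid which track to draw.
#' @return a ggplot.
#' @export
plot_sequence_trace <- function(assignments, track_uid) {
  asn <- filter(assignments, .data$track_uid == !!track_uid) |>
    arrange(.data$frame)
  if (nrow(asn) == 0) stop_data(sprintf("track '%s' not found", track_uid))
  ggplot2::ggplot(asn, ggplot2::aes(x = .data$frame, y = .data$cluster_id)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(breaks = sort(unique(asn$cluster_id))) +
    ggplot2::labs(x = "frame", y = "cluster ID", title = track_uid) +
    ggplot2::theme_minimal()
}

#' Metric intensity over the embedding ("metric heat map in UMAP space")
#' @param clusters a `behaviour_clusters` object.
#' @param metric one metric name.
#' @param dims which two embedding components to show.
#' @return a ggplot.
#' @export
plot_metric_heatmap <- function(clusters, metric, dims = c(1, 2)) {
  df <- metric_heatmap_data(clusters, metric)
  xc <- paste0("umap", dims[1]); yc <- paste0("umap", dims[2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[xc]], y = .data[[yc]],
                                   colour = .data$value)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(colour = metric) +
    ggplot2::theme_minimal()
}
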