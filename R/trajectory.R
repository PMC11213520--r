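#' Convert labelled feature records into per-track behaviour sequences
#'
#' Every cell has a behavioural cluster ID at each timepoint; ordering them by
#' frame turns each track into a categorical sequence. Gaps in a track's
#' frames are bridged by consecutive concatenation, with the gap count logged
#' per sequence. Plasticity (adjacent-frame cluster switches) is computed for
#' every sequence.
#'
#' @param assignments a tibble with `track_uid`, `frame`, `cluster_id` and
#'   (optionally) `condition` -- e.g. the `assignments` of
#'   [cluster_behaviours()], or a `behaviour_clusters` object.
#' @return a `behaviour_sequences` tibble: `track_uid`, `condition`,
#'   `sequence` (list of integer vectors), `length`, `n_gaps`, `plasticity`.
#' @export
behaviour_sequences <- function(assignments) {
  if (inherits(assignments, "behaviour_clusters")) {
    assignments <- assignments$assignments
  }
  need <- c("track_uid", "frame", "cluster_id")
  missing <- setdiff(need, names(assignments))
  if (length(missing)) {
    stop_data(sprintf("assignments lack column(s): %s",
                      paste(missing, collapse = ", ")))
  }
  has_cond <- "condition" %in% names(assignments)
  out <- assignments |>
    arrange(.data$track_uid, .data$frame) |>
    group_by(.data$track_uid) |>
    summarise(
      condition = if (has_cond) first(.data$condition) else NA_character_,
      sequence = list(as.integer(.data$cluster_id)),
      length = n(),
      n_gaps = sum(diff(.data$frame) > 1L),
      .groups = "drop"
    ) |>
    mutate(plasticity = vapply(.data$sequence, plasticity, integer(1)))
  total_gaps <- sum(out$n_gaps)
  if (total_gaps > 0) {
    inform(sprintf("behaviour_sequences: bridged %d frame gap(s) across %d track(s)",
                   total_gaps, sum(out$n_gaps > 0)))
  }
  structure(out, class = c("behaviour_sequences", class(out)))
}

#' Keep sequences of comparable length
#'
#' Edit distances between sequences of vastly different length are not
#' meaningful even after normalization, so trajectory analysis runs on a
#' length-filtered subset (inclusive bounds; the headline analysis used
#' 200--220 timepoints).
#'
#' @param sequences a `behaviour_sequences` tibble.
#' @param min_len,max_len inclusive length bounds.
#' @return the filtered tibble, with a `"length_filter_report"` attribute of
#'   kept/dropped counts per condition. Errors if nothing survives.
#' @export
filter_sequences <- function(sequences, min_len = 200L, max_len = 220L) {
  if (min_len > max_len) stop_config("`min_len` must be <= `max_len`")
  keep <- sequences$length >= min_len & sequences$length <= max_len
  out <- sequences[keep, ]
  if (nrow(out) == 0) {
    stop_data(sprintf(
      "no sequences with length in [%d, %d]; observed lengths %d-%d -- widen the bounds",
      min_len, max_len, min(sequences$length), max(sequences$length)))
  }
  report <- sequences |>
    mutate(kept = keep) |>
    count(.data$condition, .data$kept) |>
    tidyr::pivot_wider(names_from = "kept", values_from = "n", values_fill = 0L)
  attr(out, "length_filter_report") <- report
  out
}

#' Restricted Damerau--Levenshtein (optimal string alignment) distance
#'
#' Minimum number of substitutions, insertions, deletions and transpositions
#' of adjacent symbols turning one sequence into the other, with the OSA
#' restriction that no substring is edited twice. Computed by dynamic
#' programming in C++. This common library variant of Damerau--Levenshtein
#' may violate the triangle inequality, which is acceptable here because
#' downstream UMAP consumes it as a dissimilarity, not a metric.
#'
#' @param a,b integer vectors (cluster-ID sequences) or single character
#'   strings (compared character-wise). Empty sequences are allowed:
#'   `d(e, b) = length(b)`.
#' @return integer distance.
#' @examples
#' seq_edit_distance("kitten", "sitting")  # 3
#' seq_edit_distance(c(1L, 2L), c(2L, 1L)) # 1 (one transposition)
#' @export
seq_edit_distance <- function(a, b) {
  osa_distance_cpp(as_symbols(a), as_symbols(b))
}

as_symbols <- function(s) {
  if (is.character(s)) {
    stopifnot(length(s) == 1L)
    if (nchar(s) == 0) return(integer())
    return(utf8ToInt(s))
  }
  as.integer(s)
}

#' Pairwise normalized edit-distance matrix of behaviour sequences
#'
#' `d(a, b) = OSA(a, b) / max(length(a), length(b))`, in `[0, 1]`, symmetric,
#' zero diagonal; two empty sequences have distance 0.
#'
#' @param sequences a `behaviour_sequences` tibble, or a plain list of integer
#'   vectors.
#' @return a square symmetric matrix with sequence identifiers as dimnames.
#' @export
seq_distance_matrix <- function(sequences) {
  if (is.data.frame(sequences)) {
    seqs <- sequences$sequence
    ids <- sequences$track_uid
  } else {
    seqs <- sequences
    ids <- names(sequences) %||% as.character(seq_along(sequences))
  }
  if (length(seqs) < 2) stop_data("need >= 2 sequences for a distance matrix")
  d <- osa_distance_matrix_cpp(lapply(seqs, as_symbols))
  dimnames(d) <- list(ids, ids)
  d
}

#' Number of single-timepoint cluster switches in a sequence
#'
#' The plasticity measure: how many adjacent-frame positions change cluster
#' ID. An alternating sequence of length L scores L - 1; a constant sequence
#' scores 0.
#'
#' @param sequence integer vector (non-empty).
#' @return integer switch count in `[0, length - 1]`.
#' @export
plasticity <- function(sequence) {
  sequence <- as.integer(sequence)
  if (length(sequence) == 0) stop_data("plasticity of an empty sequence is undefined")
  sum(diff(sequence) != 0L)
}

#' Group behaviour sequences into trajectory IDs
#'
#' Embeds the precomputed normalized edit-distance matrix with UMAP (2
#' components) and clusters the embedding with [hdbscan()]. Sequences labelled
#' `-1` are unclustered and are excluded from downstream fingerprints and
#' exemplars.
#'
#' @param sequences a `behaviour_sequences` tibble (already length-filtered).
#' @param distances optional precomputed matrix from [seq_distance_matrix()].
#' @param n_neighbors UMAP nearest neighbours (trajectory default 15).
#' @param min_cluster_size,min_samples HDBSCAN parameters (defaults 15/10).
#' @param seed integer seed.
#' @param k_exemplars medoid exemplars kept per trajectory.
#' @param allow_single_cluster passed to [hdbscan()]; `TRUE` by default so a
#'   behaviourally homogeneous population reports one trajectory rather than
#'   none.
#' @return a `trajectory_clusters` object: `assignments` tibble (`track_uid`,
#'   `condition`, `length`, `plasticity`, `umap1`, `umap2`, `trajectory_id`),
#'   `distances`, `silhouette`, `exemplars`, `model`, `parameters`.
#' @export
cluster_trajectories <- function(sequences, distances = NULL,
                                 n_neighbors = 15L, min_cluster_size = 15L,
                                 min_samples = 10L, seed = 1L,
                                 k_exemplars = 1L,
                                 allow_single_cluster = TRUE) {
  distances <- distances %||% seq_distance_matrix(sequences)
  n <- nrow(distances)
  if (n < n_neighbors + 1) {
    stop_data(sprintf(
      "%d sequences for n_neighbors = %d; reduce n_neighbors below %d",
      n, n_neighbors, n))
  }
  emb <- embed_umap(stats::as.dist(distances), n_neighbors = n_neighbors,
                    n_components = 2L, seed = seed)
  model <- hdbscan(emb, min_cluster_size = min_cluster_size,
                   min_samples = min_samples,
                   allow_single_cluster = allow_single_cluster)
  sil <- silhouette_of_clustering(emb, model$labels, seed = seed)
  assignments <- dplyr::bind_cols(
    sequences[, intersect(c("track_uid", "condition", "length", "plasticity"),
                          names(sequences))],
    as_tibble(as.data.frame(emb)),
    tibble(trajectory_id = model$labels, lambda = model$lambda)
  )
  n_noise <- sum(model$labels < 0)
  if (n_noise > 0) {
    inform(sprintf(
      "cluster_trajectories: %d of %d sequences unclustered; excluded downstream",
      n_noise, n))
  }
  out <- structure(list(
    assignments = assignments,
    sequences = sequences,
    distances = distances,
    model = model,
    silhouette = sil,
    parameters = list(n_neighbors = n_neighbors,
                      min_cluster_size = min_cluster_size,
                      min_samples = min_samples, seed = seed,
                      allow_single_cluster = allow_single_cluster)
  ), class = "trajectory_clusters")
  out$exemplars <- trajectory_exemplars(out, k = k_exemplars)
  out
}

#' @exportS3Method base::print
print.trajectory_clusters <- function(x, ...) {
  cat(sprintf("<trajectory_clusters> %d sequences -> %d trajectory ID(s) + %d unclustered\n",
              nrow(x$assignments), x$model$n_clusters, x$model$n_noise))
  cat(sprintf("  silhouette: %s\n",
              ifelse(is.na(x$silhouette), "not computable",
                     sprintf("%.3f", x$silhouette))))
  invisible(x)
}

#' Trajectory composition fingerprints
#'
#' Two row-normalized percentage tables: (i) the share of sequences assigned
#' to each trajectory ID within each condition, and (ii) the share of
#' timepoints spent in each behavioural cluster ID within each trajectory.
#' Unclustered sequences are excluded; rows sum to 100%.
#'
#' @param trajectories a `trajectory_clusters` object.
#' @return a list of two `fingerprint` tibbles: `by_condition` and
#'   `composition`.
#' @export
trajectory_fingerprints <- function(trajectories) {
  a <- trajectories$assignments
  keep <- a$trajectory_id >= 0
  by_condition <- build_fingerprint(a$condition[keep], a$trajectory_id[keep],
                                    group_name = "condition")
  seqs <- trajectories$sequences$sequence[keep]
  traj <- rep(a$trajectory_id[keep], lengths(seqs))
  composition <- build_fingerprint(paste0("trajectory_", traj), unlist(seqs),
                                   group_name = "trajectory_id")
  list(by_condition = by_condition, composition = composition)
}

#' Plasticity summaries and rank tests between groups
#'
#' Summarises the switch-count distribution per trajectory ID or per
#' condition (median, IQR, range, n) and runs Kruskal--Wallis plus pairwise
#' Bonferroni-corrected rank-sum tests. Grouping by trajectory excludes
#' unclustered sequences; grouping by condition keeps them, since
#' condition-level switching is computed independently of trajectory IDs.
#'
#' @param trajectories a `trajectory_clusters` object.
#' @param by `"trajectory"` or `"condition"`.
#' @return a list: `summary` tibble and a `rank_test_report` (`tests`).
#' @export
compare_plasticity <- function(trajectories, by = c("trajectory", "condition")) {
  by <- match.arg(by)
  a <- trajectories$assignments
  if (by == "trajectory") {
    a <- filter(a, .data$trajectory_id >= 0)
    a$group <- paste0("trajectory_", a$trajectory_id)
  } else {
    a$group <- a$condition
  }
  summary <- a |>
    group_by(.data$group) |>
    summarise(
      n = n(),
      median = median(.data$plasticity),
      q1 = unname(quantile(.data$plasticity, 0.25)),
      q3 = unname(quantile(.data$plasticity, 0.75)),
      min = min(.data$plasticity),
      max = max(.data$plasticity),
      .groups = "drop"
    )
  tests <- if (dplyr::n_distinct(a$group) >= 2 &&
               all(table(a$group) >= 2)) {
    rank_tests(split(a$plasticity, a$group))
  }
  list(summary = summary, tests = tests)
}

#' Medoid exemplar sequences per trajectory ID
#'
#' For each trajectory, the `k` member sequences minimizing the summed
#' normalized edit distance to their co-members (medoids); ties broken by
#' stable record order. Trajectories smaller than `k` return all members.
#'
#' @param trajectories a `trajectory_clusters` object.
#' @param k exemplars per trajectory.
#' @return a tibble: `trajectory_id`, `rank`, `track_uid`, `condition`,
#'   `plasticity`, `medoid_cost` (mean distance to co-members).
#' @export
trajectory_exemplars <- function(trajectories, k = 1L) {
  a <- trajectories$assignments
  d <- trajectories$distances
  ids <- sort(unique(a$trajectory_id[a$trajectory_id >= 0]))
  bind_rows(lapply(ids, function(tid) {
    members <- which(a$trajectory_id == tid)
    cost <- if (length(members) > 1) {
      rowSums(d[members, members, drop = FALSE]) / (length(members) - 1)
    } else 0
    ord <- order(cost, seq_along(members))[seq_len(min(k, length(members)))]
    tibble(
      trajectory_id = tid, rank = seq_along(ord),
      track_uid = a$track_uid[members[ord]],
      condition = a$condition[members[ord]],
      plasticity = a$plasticity[members[ord]],
      medoid_cost = cost[ord]
    )
  }))
}

#' Export behaviour sequences as tidy CSV
#' @param sequences a `behaviour_sequences` tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_sequences <- function(sequences, path) {
  df <- sequences
  df$sequence <- vapply(df$sequence, paste, character(1), collapse = ",")
  write.csv(as.data.frame(df), path, row.names = FALSE)
  invisible(path)
}
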