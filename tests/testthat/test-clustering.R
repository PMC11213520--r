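# a small labelled feature table: two planted phenotypes differing in a
# single metric block, used across the clustering unit tests
planted_features <- function(n_per = 120, seed = 5, delta = 6) {
  spec <- synthetic_experiment_spec(
    conditions = list(
      slow = list(regimes = list(regime_stationary()), proportions = 1),
      fast = list(regimes = list(regime_persistent(speed = delta)),
                  proportions = 1)
    ),
    n_tracks = 10L, len_range = c(12L, 12L), seed = seed
  )
  sim <- simulate_tracks(spec)
  compute_features(sim$tracks, window_frames = 8, frame_interval = 40)
}

test_that("z-scaling centres every included metric and honours exclusions", {
  ft <- suppressWarnings(planted_features())
  sc <- suppressWarnings(scale_features(ft, c("turn_angle", "ripley_k")))
  expect_false(any(c("turn_angle", "ripley_k") %in% colnames(sc$matrix)))
  expect_lte(ncol(sc$matrix), 26)
  mu <- colMeans(sc$matrix)
  sdv <- apply(sc$matrix, 2, sd)
  expect_true(all(abs(mu) < 1e-6))
  expect_true(all(abs(sdv - 1) < 1e-6))
  expect_equal(nrow(sc$index), nrow(ft))
})

test_that("constant columns are dropped with a warning and all-constant errors", {
  df <- tibble::tibble(
    condition = "a", replicate = "r", track_uid = "t", frame = 1:10,
    v1 = rnorm(10), v2 = rep(3, 10)
  )
  attr(df, "catalogue") <- tibble::tibble(name = c("v1", "v2"),
                                          group = "x", description = "")
  expect_warning(sc <- scale_features(df, character()), "v2")
  expect_identical(colnames(sc$matrix), "v1")
  df$v1 <- rep(1, 10)
  expect_error(suppressWarnings(scale_features(df, character())),
               "zero variance")
})

test_that("UMAP separates planted blobs, is deterministic, and co-locates duplicates", {
  withr::with_seed(8, {
    X <- rbind(matrix(rnorm(120 * 26), ncol = 26),
               matrix(rnorm(120 * 26, 20), ncol = 26))
  })
  e1 <- embed_umap(X, n_neighbors = 15, seed = 42)
  expect_equal(dim(e1), c(240, 3))
  centroid_a <- colMeans(e1[1:120, ])
  centroid_b <- colMeans(e1[121:240, ])
  spread <- mean(sqrt(rowSums(sweep(e1[1:120, ], 2, centroid_a)^2)))
  gap <- sqrt(sum((centroid_a - centroid_b)^2))
  expect_gt(gap, 2 * spread)

  e2 <- embed_umap(X, n_neighbors = 15, seed = 42)
  expect_identical(e1, e2)

  # duplicated rows land on top of each other relative to the data spread
  Xd <- rbind(X, X[1:5, ])
  ed <- embed_umap(Xd, n_neighbors = 15, seed = 1)
  dup_d <- sqrt(rowSums((ed[241:245, ] - ed[1:5, ])^2))
  expect_lt(max(dup_d), 0.05 * gap)

  expect_error(embed_umap(X[1:10, ], n_neighbors = 15), "n_neighbors")
})

test_that("silhouette scores behave at the extremes", {
  withr::with_seed(4, {
    tight <- rbind(cbind(rnorm(100, 0, 0.1), rnorm(100, 0, 0.1)),
                   cbind(rnorm(100, 50, 0.1), rnorm(100, 50, 0.1)))
  })
  lab <- rep(0:1, each = 100)
  expect_gt(silhouette_of_clustering(tight, lab), 0.9)

  one <- silhouette_of_clustering(tight, rep(0L, 200))
  expect_true(is.na(one))
  expect_match(attr(one, "reason"), "not computable")

  rand_lab <- withr::with_seed(5, sample(0:1, 100, replace = TRUE))
  blob <- withr::with_seed(6, cbind(rnorm(100), rnorm(100)))
  expect_lt(silhouette_of_clustering(blob, rand_lab), 0.1)
})

test_that("behavioural clustering recovers planted phenotypes end to end", {
  ft <- suppressWarnings(planted_features())
  cl <- suppressWarnings(cluster_behaviours(
    ft, n_neighbors = 20, min_cluster_size = 60, min_samples = 15, seed = 2
  ))
  expect_s3_class(cl, "behaviour_clusters")
  expect_equal(nrow(cl$assignments), nrow(ft))
  expect_gte(cl$model$n_clusters, 2)
  # condition is the phenotype ground truth here
  keep <- cl$assignments$cluster_id >= 0
  expect_gte(ari(cl$assignments$cluster_id[keep],
                 cl$assignments$condition[keep]), 0.8)
  gl <- glance(cl)
  expect_equal(gl$n_records, nrow(ft))
  expect_true(gl$silhouette > 0 || is.na(gl$silhouette))
})

test_that("clustering is label-permutation invariant in its summaries and deterministic", {
  ft <- suppressWarnings(planted_features(seed = 9))
  cl1 <- suppressWarnings(cluster_behaviours(
    ft, n_neighbors = 20, min_cluster_size = 60, min_samples = 15, seed = 3
  ))
  cl2 <- suppressWarnings(cluster_behaviours(
    ft, n_neighbors = 20, min_cluster_size = 60, min_samples = 15, seed = 3
  ))
  expect_identical(cl1$assignments$cluster_id, cl2$assignments$cluster_id)
  expect_identical(cl1$silhouette, cl2$silhouette)

  # renumbering clusters moves no fingerprint mass
  labs <- cl1$assignments$cluster_id
  perm <- max(labs) - labs
  perm[labs < 0] <- -1L
  fp1 <- cluster_fingerprint(labs, cl1$assignments$condition)
  fp2 <- cluster_fingerprint(perm, cl1$assignments$condition)
  expect_equal(sort(unlist(fp1[1, -1])), sort(unlist(fp2[1, -1])),
               ignore_attr = TRUE)
  s1 <- silhouette_of_clustering(as.matrix(cl1$assignments[, c("umap1", "umap2", "umap3")]), labs)
  s2 <- silhouette_of_clustering(as.matrix(cl1$assignments[, c("umap1", "umap2", "umap3")]), perm)
  expect_equal(s1, s2, ignore_attr = TRUE)
})

test_that("exemplars are cluster members, density-central, and clipped to size", {
  ft <- suppressWarnings(planted_features(seed = 12))
  cl <- suppressWarnings(cluster_behaviours(
    ft, n_neighbors = 20, min_cluster_size = 60, min_samples = 15, seed = 4
  ))
  ex <- extract_exemplars(cl, k = 3)
  expect_true(all(ex$cluster_id >= 0))
  counts <- table(ex$cluster_id)
  expect_true(all(counts <= 3))
  # exemplar lambda is maximal within its cluster
  for (cid in unique(ex$cluster_id)) {
    members <- cl$assignments[cl$assignments$cluster_id == cid, ]
    expect_equal(max(ex$lambda[ex$cluster_id == cid]), max(members$lambda))
  }
  # k larger than the cluster returns all members
  ex_all <- extract_exemplars(cl, k = 10^6)
  expect_equal(nrow(ex_all), sum(cl$assignments$cluster_id >= 0))
})

test_that("top contributing metrics find a planted single-metric contrast", {
  withr::with_seed(30, {
    z <- matrix(rnorm(400 * 5), ncol = 5,
                dimnames = list(NULL, c("speed", "area", "m3", "m4", "m5")))
    z[201:400, "speed"] <- z[201:400, "speed"] + 3
  })
  sc <- structure(list(matrix = z), class = "scaled_features")
  labels <- rep(0:1, each = 200)
  top <- top_contributing_metrics(sc, k = 3, labels = labels)
  expect_equal(top$metric[top$cluster_id == 1 & top$rank == 1], "speed")
  expect_gt(top$score[top$cluster_id == 1 & top$rank == 1], 2)

  # identical generating distributions: all contributions small
  withr::with_seed(31, {
    z0 <- matrix(rnorm(400 * 5), ncol = 5,
                 dimnames = list(NULL, paste0("m", 1:5)))
  })
  sc0 <- structure(list(matrix = z0), class = "scaled_features")
  top0 <- top_contributing_metrics(sc0, k = 5, labels = labels)
  expect_lt(max(top0$score), 0.2)

  # k beyond the metric count returns everything ranked
  top_all <- top_contributing_metrics(sc, k = 99, labels = labels)
  expect_equal(sum(top_all$cluster_id == 0), 5)
})

test_that("fingerprints are row-normalized percentages including unclustered", {
  fp <- cluster_fingerprint(c(0L, 0L, 1L, 1L), rep("a", 4))
  expect_equal(unlist(fp[1, c("0", "1")]), c("0" = 50, "1" = 50))

  fp_noise <- cluster_fingerprint(rep(-1L, 6), rep("a", 6))
  expect_equal(fp_noise$unclustered, 100)

  labs <- withr::with_seed(7, sample(c(-1L, 0L, 1L, 2L), 300, replace = TRUE))
  grp <- rep(c("x", "y", "z"), each = 100)
  fp_r <- cluster_fingerprint(labs, grp)
  expect_equal(unname(rowSums(fp_r[, -1])), rep(100, 3), tolerance = 1e-9)
  expect_error(cluster_fingerprint(integer(), character()), "zero")
})

test_that("metric heatmap data aligns scaled values with the embedding", {
  ft <- suppressWarnings(planted_features(seed = 20))
  cl <- suppressWarnings(cluster_behaviours(
    ft, n_neighbors = 20, min_cluster_size = 60, min_samples = 15, seed = 5
  ))
  hm <- metric_heatmap_data(cl, "speed")
  expect_equal(nrow(hm), nrow(ft))
  expect_equal(hm$value, unname(cl$scaled$matrix[, "speed"]))
  # the planted fast phenotype separates along the embedding: speed values
  # correlate with position along the axis separating the two groups
  fast <- cl$assignments$condition == "fast"
  expect_gt(abs(cor(hm$value, fast)), 0.5)
  expect_error(metric_heatmap_data(cl, "not_a_metric"), "not_a_metric")
})
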