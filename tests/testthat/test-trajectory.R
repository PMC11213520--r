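test_that("edit distance matches hand values and the independent DP oracle", {
  expect_equal(seq_edit_distance("abc", "abc"), 0)
  expect_equal(seq_edit_distance("ab", "ba"), 1)       # one transposition
  expect_equal(seq_edit_distance("kitten", "sitting"), 3)
  expect_equal(seq_edit_distance("", "abc"), 3)
  expect_equal(seq_edit_distance(integer(), integer()), 0)

  withr::with_seed(14, {
    for (i in 1:500) {
      a <- sample(0:7, sample(0:20, 1), replace = TRUE)
      b <- sample(0:7, sample(0:20, 1), replace = TRUE)
      expect_identical(seq_edit_distance(a, b), osa_oracle(a, b))
    }
  })
})

test_that("edit distance is invariant under symbol relabelling", {
  withr::with_seed(15, {
    for (i in 1:50) {
      a <- sample(0:5, 30, replace = TRUE)
      b <- sample(0:5, 25, replace = TRUE)
      perm <- sample(0:5)
      expect_identical(seq_edit_distance(perm[a + 1], perm[b + 1]),
                       seq_edit_distance(a, b))
    }
  })
})

test_that("normalized distance matrix is symmetric, bounded and zero-diagonal", {
  seqs <- list(a = c(1L, 2L, 3L), b = c(1L, 2L, 3L), c = c(4L, 5L, 6L),
               d = utf8ToInt("kitten"), e = utf8ToInt("sitting"))
  d <- seq_distance_matrix(seqs)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 1)          # disjoint alphabets, equal length
  expect_equal(d["d", "e"], 3 / 7)

  withr::with_seed(16, {
    rand <- lapply(1:30, function(i) sample(0:7, sample(5:20, 1), replace = TRUE))
  })
  dr <- seq_distance_matrix(rand)
  for (k in 1:20) {
    i <- sample(30, 1); j <- sample(30, 1)
    expect_equal(dr[i, j],
                 osa_oracle(rand[[i]], rand[[j]]) /
                   max(length(rand[[i]]), length(rand[[j]])))
  }
})

test_that("sequences are built per track in frame order with gaps logged", {
  asn <- tibble::tibble(
    track_uid = c(rep("t1", 5), rep("t2", 3)),
    condition = c(rep("a", 5), rep("b", 3)),
    frame = c(0:4, c(0L, 1L, 3L)),       # t2 has a gap
    cluster_id = c(2L, 2L, 3L, 3L, 3L, 1L, 1L, 1L)
  )
  seqs <- suppressMessages(behaviour_sequences(asn))
  expect_equal(nrow(seqs), 2)
  expect_equal(seqs$sequence[[which(seqs$track_uid == "t1")]],
               c(2L, 2L, 3L, 3L, 3L))
  expect_equal(seqs$length, c(5L, 3L))
  expect_equal(seqs$n_gaps, c(0L, 1L))
  expect_equal(seqs$plasticity, c(1L, 0L))
})

test_that("length filtering is inclusive and reports per condition", {
  seqs <- tibble::tibble(
    track_uid = paste0("t", 1:5),
    condition = "a",
    sequence = lapply(c(150, 200, 210, 220, 230), function(n) rep(0L, n)),
    length = c(150L, 200L, 210L, 220L, 230L),
    plasticity = 0L
  )
  kept <- filter_sequences(seqs, 200, 220)
  expect_equal(nrow(kept), 3)
  expect_equal(nrow(filter_sequences(seqs, 1, 10^9)), 5)
  expect_error(filter_sequences(seqs, 300, 400), "widen")
  expect_error(filter_sequences(seqs, 10, 5), "min_len")
})

test_that("plasticity counts adjacent switches exactly", {
  expect_equal(plasticity(c(1, 1, 1)), 0)
  expect_equal(plasticity(c(0, 0, 1, 1, 0)), 2)
  for (L in c(2, 17, 100)) {
    expect_equal(plasticity(rep_len(c(0L, 1L), L)), L - 1)
  }
  # relabelling symbols by any bijection preserves switch counts
  withr::with_seed(18, {
    s <- sample(0:3, 50, replace = TRUE)
    perm <- sample(0:3)
    expect_equal(plasticity(perm[s + 1]), plasticity(s))
  })
  expect_error(plasticity(integer()), "empty")
})

test_that("planted grammars are recovered as four trajectories", {
  seqs <- make_grammar_sequences(n_per = 30, len = 200, seed = 44)
  d <- seq_distance_matrix(seqs)
  tr <- suppressMessages(cluster_trajectories(
    seqs, distances = d, n_neighbors = 15, min_cluster_size = 15,
    min_samples = 10, seed = 1
  ))
  keep <- tr$assignments$trajectory_id >= 0
  expect_equal(tr$model$n_clusters, 4)
  expect_gte(ari(tr$assignments$trajectory_id[keep], seqs$grammar[keep]), 0.9)

  # determinism
  tr2 <- suppressMessages(cluster_trajectories(
    seqs, distances = d, n_neighbors = 15, min_cluster_size = 15,
    min_samples = 10, seed = 1
  ))
  expect_identical(tr$assignments$trajectory_id, tr2$assignments$trajectory_id)
})

test_that("all-identical sequences collapse to a single trajectory", {
  seqs <- tibble::tibble(
    track_uid = sprintf("t%02d", 1:40),
    condition = "a",
    sequence = lapply(1:40, function(i) rep(2L, 50)),
    length = 50L,
    plasticity = 0L
  )
  tr <- suppressMessages(cluster_trajectories(
    seqs, n_neighbors = 10, min_cluster_size = 10, min_samples = 5, seed = 2
  ))
  expect_equal(tr$model$n_clusters, 1)
  fp <- trajectory_fingerprints(tr)
  expect_equal(unname(unlist(fp$composition[1, -1])), 100)  # all cluster 2
})

test_that("trajectory fingerprints are conserved and composition matches content", {
  seqs <- make_grammar_sequences(n_per = 20, len = 60, seed = 3)
  tr <- suppressMessages(cluster_trajectories(
    seqs, n_neighbors = 10, min_cluster_size = 10, min_samples = 5, seed = 5
  ))
  fp <- trajectory_fingerprints(tr)
  expect_equal(unname(rowSums(fp$by_condition[, -1])),
               rep(100, nrow(fp$by_condition)), tolerance = 1e-9)
  expect_equal(unname(rowSums(fp$composition[, -1])),
               rep(100, nrow(fp$composition)), tolerance = 1e-9)
})

test_that("plasticity comparisons split planted grammars and match a sort oracle", {
  seqs <- make_grammar_sequences(n_per = 20, len = 100, seed = 6)
  tr <- suppressMessages(cluster_trajectories(
    seqs, n_neighbors = 10, min_cluster_size = 10, min_samples = 5, seed = 7
  ))
  cmp <- compare_plasticity(tr, by = "trajectory")
  # medians equal an independent per-group sort-based median
  a <- tr$assignments[tr$assignments$trajectory_id >= 0, ]
  for (g in unique(a$trajectory_id)) {
    v <- sort(a$plasticity[a$trajectory_id == g])
    n <- length(v)
    manual <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
    expect_equal(cmp$summary$median[cmp$summary$group == paste0("trajectory_", g)],
                 manual)
  }
  meds <- sort(cmp$summary$median)
  expect_equal(meds[1], 0)        # constant grammar
  expect_equal(max(meds), 99)     # alternating grammar: length - 1
})

test_that("trajectory exemplars are medoids", {
  seqs <- make_grammar_sequences(n_per = 15, len = 40, seed = 8)
  d <- seq_distance_matrix(seqs)
  tr <- suppressMessages(cluster_trajectories(
    seqs, distances = d, n_neighbors = 8, min_cluster_size = 8,
    min_samples = 4, seed = 9
  ))
  ex <- trajectory_exemplars(tr, k = 1)
  a <- tr$assignments
  for (r in seq_len(nrow(ex))) {
    members <- which(a$trajectory_id == ex$trajectory_id[r])
    costs <- rowSums(d[members, members, drop = FALSE])
    chosen <- which(a$track_uid[members] == ex$track_uid[r])
    expect_equal(costs[chosen], min(costs), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # exemplar of the constant grammar never switches
  const_traj <- ex$trajectory_id[ex$track_uid %in%
                                   seqs$track_uid[seqs$grammar == "constant"]]
  if (length(const_traj)) {
    expect_equal(ex$plasticity[ex$trajectory_id == const_traj[1]], 0)
  }
})

test_that("sequences export to tidy CSV", {
  seqs <- make_grammar_sequences(n_per = 2, len = 10, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  export_sequences(seqs, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 8)
  expect_match(back$sequence[1], "^0(,0){9}$")
})
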