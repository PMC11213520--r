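test_that("tiny-sample bootstrap agrees with the exhaustive resample space", {
  a <- c(1, 2, 3); b <- c(11, 12, 13)
  # exhaustive oracle: all 27 x 27 within-group resamples with replacement
  grids <- expand.grid(i = 1:3, j = 1:3, k = 1:3)
  meds_a <- apply(grids, 1, function(g) median(a[g]))
  meds_b <- apply(grids, 1, function(g) median(b[g]))
  all_diffs <- outer(meds_b, meds_a, "-")
  expect_equal(min(all_diffs), 8)   # smallest achievable difference
  expect_equal(max(all_diffs), 12)

  es <- bootstrap_effect_size(a, b, n_boot = 1000, seed = 4)
  expect_equal(es$estimate, 10)
  expect_true(all(es$boot >= 8 & es$boot <= 12))
  expect_length(es$boot, 1000)
  # bootstrap distribution is a subsample of the exhaustive support
  expect_true(all(es$boot %in% sort(unique(as.vector(all_diffs)))))
})

test_that("identical samples give a zero estimate with a CI containing 0", {
  x <- withr::with_seed(5, rnorm(200))
  es <- bootstrap_effect_size(x, x, n_boot = 500, seed = 6)
  expect_equal(es$estimate, 0)
  expect_lte(es$conf.low, 0)
  expect_gte(es$conf.high, 0)
  expect_lte(es$conf.low, es$conf.high)
})

test_that("effect sizes are antisymmetric, seed-deterministic and location-equivariant", {
  withr::with_seed(9, {
    a <- rnorm(80); b <- rnorm(80, 0.5)
  })
  ab <- bootstrap_effect_size(a, b, n_boot = 300, seed = 7)
  ba <- bootstrap_effect_size(b, a, n_boot = 300, seed = 7)
  expect_equal(ab$estimate, -ba$estimate)

  again <- bootstrap_effect_size(a, b, n_boot = 300, seed = 7)
  expect_identical(ab$boot, again$boot)

  shift_both <- bootstrap_effect_size(a + 5, b + 5, n_boot = 300, seed = 7)
  expect_equal(shift_both$estimate, ab$estimate)
  shift_one <- bootstrap_effect_size(a, b + 5, n_boot = 300, seed = 7)
  expect_equal(shift_one$estimate, ab$estimate + 5)

  expect_error(bootstrap_effect_size(numeric(), b), "non-empty")
  expect_warning(bootstrap_effect_size(a, b, n_boot = 50), "n_boot")
})

test_that("tidy and glance summarise effect sizes", {
  x <- withr::with_seed(8, rnorm(50, sd = 0.1))
  es <- bootstrap_effect_size(x, x + 2, n_boot = 200, seed = 1,
                              names = c(control = "icam", test = "vcam"))
  td <- tidy(es)
  expect_equal(td$estimate, 2)
  expect_equal(td$control, "icam")
  gl <- glance(es)
  expect_equal(gl$n_boot, 200)
  expect_true(gl$excludes_zero)
})

test_that("per-frame effect sizes recover a constant shift and mask tiny groups", {
  withr::with_seed(12, {
    base <- tibble::tibble(
      condition = "a",
      frame = rep(0:9, each = 30),
      value = rnorm(300)
    )
    shifted <- dplyr::mutate(base, condition = "b", value = value + 1)
  })
  ft <- dplyr::bind_rows(base, shifted)
  tp <- timeplot_difference(ft, "value", control = "a", n_boot = 200, seed = 3)
  eff <- tp$effect[tp$condition == "b"]
  expect_true(all(abs(eff - 1) < 1e-9))  # exact constant shift per frame
  expect_true(all(tp$effect_low[tp$condition == "b"] <= eff))

  # starve condition b at frame 9
  ft2 <- dplyr::bind_rows(
    ft[ft$condition == "a" | ft$frame != 9, ],
    dplyr::slice_head(ft[ft$condition == "b" & ft$frame == 9, ], n = 2)
  )
  tp2 <- timeplot_difference(ft2, "value", control = "a", n_boot = 100, seed = 3)
  expect_true(tp2$masked[tp2$condition == "b" & tp2$frame == 9])
  expect_false(tp2$masked[tp2$condition == "b" & tp2$frame == 0])
})

test_that("null timeplots keep zero inside the effect band at most frames", {
  covered <- withr::with_seed(99, {
    vapply(1:40, function(r) {
      ft <- tibble::tibble(
        condition = rep(c("a", "b"), each = 150),
        frame = rep(rep(0:4, each = 30), 2),
        value = rnorm(300)
      )
      tp <- timeplot_difference(ft, "value", control = "a", n_boot = 200,
                                seed = r)
      b <- tp[tp$condition == "b", ]
      mean(b$effect_low <= 0 & b$effect_high >= 0)
    }, numeric(1))
  })
  expect_gte(mean(covered), 0.9)
})

test_that("rank tests reproduce the exact permutation oracle and Bonferroni rule", {
  rep2 <- rank_tests(list(g1 = c(1, 2, 3, 4, 5), g2 = c(10, 11, 12, 13, 14)))
  expect_equal(rep2$pairwise$p_raw, 2 / 252, tolerance = 1e-12)
  expect_equal(rep2$pairwise$p_adj, rep2$pairwise$p_raw)  # no correction for 2 groups

  withr::with_seed(2, {
    g <- list(a = rnorm(12), b = rnorm(12), c = rnorm(12, 2))
  })
  rep3 <- rank_tests(g)
  expect_equal(nrow(rep3$pairwise), 3)
  for (k in 1:3) {
    expect_equal(rep3$pairwise$p_adj[k], min(1, 3 * rep3$pairwise$p_raw[k]))
  }
  expect_false(rep3$degenerate)
  expect_equal(unname(rep3$n), c(12L, 12L, 12L))

  same <- withr::with_seed(4, rnorm(30))
  null_rep <- rank_tests(list(a = same, b = same))
  expect_gt(null_rep$kruskal$p_value, 0.5)

  degen <- rank_tests(list(a = rep(1, 5), b = rep(1, 5)))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$kruskal$statistic))

  expect_error(rank_tests(list(a = 1:5)), "2 groups")
  expect_error(rank_tests(list(a = 1:5, b = 2)), ">= 2 observations")
})

test_that("rank tests accept the data-frame interface", {
  df <- tibble::tibble(g = rep(c("x", "y"), each = 5),
                       v = c(1:5, 10:14))
  rep_ <- rank_tests(df, value = "v", group = "g")
  expect_equal(rep_$pairwise$p_raw, 2 / 252, tolerance = 1e-12)
  gl <- glance(rep_)
  expect_equal(gl$n_groups, 2)
})
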