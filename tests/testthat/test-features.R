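test_that("morphology matches closed forms for circle, ellipse and square", {
  m <- contour_morphology(make_circle(10, n = 360))
  expect_equal(m[["area"]], 100 * pi, tolerance = 0.01)
  expect_equal(m[["circularity"]], 1, tolerance = 0.01)
  expect_lt(m[["eccentricity"]], 0.05)
  expect_equal(m[["aspect_ratio"]], 1, tolerance = 0.01)
  expect_equal(m[["equivalent_diameter"]], 20, tolerance = 0.01)
  expect_equal(m[["major_axis_length"]], 20, tolerance = 0.01)

  e <- contour_morphology(make_ellipse(20, 10, n = 720))
  expect_equal(e[["aspect_ratio"]], 2, tolerance = 0.01)
  expect_equal(e[["eccentricity"]], sqrt(1 - 0.25), tolerance = 0.01)
  expect_equal(e[["area"]], pi * 200, tolerance = 0.01)

  s <- contour_morphology(make_square(10))
  expect_equal(s[["area"]], 100)
  expect_equal(s[["perimeter"]], 40)
  expect_equal(s[["extent"]], 1)
  expect_equal(s[["solidity"]], 1)
  expect_equal(s[["bbox_area"]], 100)
})

test_that("orientation tracks the major axis and stays in (-pi/2, pi/2]", {
  for (phi in c(-1.2, -0.4, 0, 0.7, 1.4)) {
    m <- contour_morphology(make_ellipse(20, 10, phi = phi))
    expect_equal(m[["orientation"]], phi, tolerance = 1e-3)
    expect_true(m[["orientation"]] > -pi / 2 && m[["orientation"]] <= pi / 2)
  }
})

test_that("a non-convex shape has solidity below 1 and degenerate input errors", {
  m <- contour_morphology(make_c_shape())
  expect_lt(m[["solidity"]], 1)
  expect_error(contour_morphology(cbind(c(0, 1), c(0, 1))), "3")
  expect_error(contour_morphology(cbind(c(0, 1, 2), c(0, 0, 0))), "area|degenerate")
})

test_that("morphology is scale-equivariant", {
  p <- make_ellipse(14, 6, phi = 0.5)
  m1 <- contour_morphology(p)
  m2 <- contour_morphology(p * 3)
  expect_equal(m2[["area"]], 9 * m1[["area"]])
  expect_equal(m2[["perimeter"]], 3 * m1[["perimeter"]])
  for (inv in c("eccentricity", "aspect_ratio", "circularity", "solidity",
                "extent", "orientation")) {
    expect_equal(m2[[inv]], m1[[inv]], tolerance = 1e-9)
  }
})

test_that("straight-line and out-and-back walkers have exact kinematic identities", {
  # 2 um per 40 s frame = 3 um/min
  tr <- make_track_table(straight_walk(8, step = 2))
  k <- window_kinematics(tr, window_frames = 8, frame_interval = 40)
  last <- k[k$frame == 7, ]
  expect_equal(last$speed, 3)
  expect_equal(last$directedness, 1)
  expect_equal(last$outreach_ratio, 1)
  expect_equal(last$cumulative_length, 14)
  expect_equal(last$euclidean_distance, 14)
  expect_true(last$window_complete)
  expect_false(k$window_complete[k$frame == 3])

  tr2 <- make_track_table(out_and_back_walk(4, step = 2))
  k2 <- window_kinematics(tr2, window_frames = 9, frame_interval = 40)
  last2 <- k2[k2$frame == 8, ]
  expect_equal(last2$euclidean_distance, 0)
  expect_equal(last2$directedness, 0)
  expect_equal(last2$outreach_ratio, 0.5)
})

test_that("directedness and outreach never exceed 1 and reverse-time invariants hold", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      pos <- cbind(cumsum(rnorm(15)), cumsum(rnorm(15)))
      tr <- make_track_table(pos)
      k <- window_kinematics(tr, window_frames = 6, frame_interval = 40)
      expect_true(all(k$directedness <= 1 + 1e-12))
      expect_true(all(k$outreach_ratio <= 1 + 1e-12))
      expect_true(all(k$directedness >= 0 & k$outreach_ratio >= 0))
      # full-window path length / net displacement unchanged under reversal
      kr <- window_kinematics(make_track_table(pos[nrow(pos):1, ]),
                              window_frames = nrow(pos), frame_interval = 40)
      kfull <- window_kinematics(tr, window_frames = nrow(pos),
                                 frame_interval = 40)
      i <- nrow(pos)
      expect_equal(kr$cumulative_length[i], kfull$cumulative_length[i])
      expect_equal(kr$euclidean_distance[i], kfull$euclidean_distance[i])
      expect_equal(kr$directedness[i], kfull$directedness[i])
    }
  })
})

test_that("window clipping: metrics at frame >= W-1 ignore earlier history", {
  withr::with_seed(3, {
    pos <- cbind(cumsum(rnorm(20)), cumsum(rnorm(20)))
  })
  full <- window_kinematics(make_track_table(pos), 5, 40)
  tail_only <- window_kinematics(make_track_table(pos[10:20, ]), 5, 40)
  # frame 14 of the full track is frame 5 of the truncated one: same window
  got <- full[full$frame == 14, setdiff(names(full), c("frame", "window_complete"))]
  want <- tail_only[tail_only$frame == 5,
                    setdiff(names(tail_only), c("frame", "window_complete"))]
  expect_equal(as.data.frame(got), as.data.frame(want), tolerance = 1e-12)
})

test_that("windowed MSD matches the Brownian closed form over many windows", {
  # ensemble of short Brownian tracks; lag = floor(W/2) frames
  D <- 1.5           # um^2/min
  W <- 8L
  dt <- 40           # s
  n_tracks <- 2000L
  msd <- withr::with_seed(21, {
    vapply(seq_len(n_tracks), function(i) {
      tr <- simulate_track(regime_brownian(diffusion = D), W, dt)
      k <- window_kinematics(tr, W, dt)
      k$msd[W]
    }, numeric(1))
  })
  lag_min <- (W %/% 2) * dt / 60
  expected <- 4 * D * lag_min
  se <- sd(msd) / sqrt(n_tracks)
  expect_lt(abs(mean(msd) - expected), 3 * se)
})

test_that("spatial density counts neighbours and flags singletons", {
  single <- tibble::tibble(x_um = 5, y_um = 5)
  s1 <- spatial_density(single, radius_um = 15)
  expect_equal(s1$ripley_k, 0)
  expect_gt(s1$nn_distance, 0)

  tri <- tibble::tibble(x_um = c(0, 10, 5), y_um = c(0, 0, 10 * sqrt(3) / 2))
  s3 <- spatial_density(tri, radius_um = 15)
  # all three mutual distances are 10 < 15: two neighbours each
  lambda <- 3 / (10 * (10 * sqrt(3) / 2))
  expect_equal(s3$ripley_k, rep(2 / lambda, 3))
  expect_equal(s3$nn_distance, rep(10, 3))
  expect_error(spatial_density(tri, radius_um = -1), "radius")
})

test_that("Ripley K approximates pi r^2 under complete spatial randomness", {
  # large field relative to radius keeps the uncorrected edge bias well
  # inside the Monte-Carlo band
  r <- 30; L <- 4000; n <- 500; reps <- 100
  k_means <- withr::with_seed(13, {
    vapply(seq_len(reps), function(i) {
      pts <- tibble::tibble(x_um = runif(n, 0, L), y_um = runif(n, 0, L))
      mean(spatial_density(pts, radius_um = r)$ripley_k)
    }, numeric(1))
  })
  se <- sd(k_means) / sqrt(reps)
  expect_lt(abs(mean(k_means) - pi * r^2), 3 * se)
})

test_that("the feature table is complete, ordered and scale-equivariant", {
  spec <- synthetic_experiment_spec(n_tracks = 4L, len_range = c(12L, 15L),
                                    seed = 31)
  sim <- simulate_tracks(spec)
  ft <- compute_features(sim$tracks, window_frames = 8, frame_interval = 40)
  cat <- metric_catalogue()
  expect_equal(nrow(cat), 28)
  expect_true(all(cat$name %in% names(ft)))
  expect_equal(nrow(ft), nrow(sim$tracks))
  expect_false(anyNA(ft[cat$name]))
  expect_true(all(ft$area > 0))
  expect_true(all(ft$directedness >= 0 & ft$directedness <= 1))

  # doubling the spatial scale: areas x4, lengths x2, ratios unchanged
  scaled_tracks <- sim$tracks
  scaled_tracks$x_um <- scaled_tracks$x_um * 2
  scaled_tracks$y_um <- scaled_tracks$y_um * 2
  scaled_tracks$contour <- lapply(scaled_tracks$contour, function(p) p * 2)
  ft2 <- compute_features(scaled_tracks, window_frames = 8, frame_interval = 40)
  expect_equal(ft2$area, 4 * ft$area, tolerance = 1e-9)
  expect_equal(ft2$cumulative_length, 2 * ft$cumulative_length, tolerance = 1e-9)
  expect_equal(ft2$speed, 2 * ft$speed, tolerance = 1e-9)
  expect_equal(ft2$directedness, ft$directedness, tolerance = 1e-9)
  expect_equal(ft2$outreach_ratio, ft$outreach_ratio, tolerance = 1e-9)
  expect_equal(ft2$eccentricity, ft$eccentricity, tolerance = 1e-9)
  expect_equal(ft2$aspect_ratio, ft$aspect_ratio, tolerance = 1e-9)
})

test_that("stationary fixtures yield near-zero kinematics and walkers order by speed", {
  spec <- synthetic_experiment_spec(
    conditions = list(
      still = list(regimes = list(regime_stationary(jitter = 0)), proportions = 1),
      movers = list(regimes = list(regime_persistent(speed = 5)), proportions = 1)
    ),
    n_tracks = 5L, len_range = c(12L, 12L), seed = 17
  )
  sim <- simulate_tracks(spec)
  ft <- compute_features(sim$tracks, window_frames = 8, frame_interval = 40)
  still <- ft[ft$condition == "still", ]
  expect_true(all(still$speed < 1e-9))
  expect_true(all(still$directedness < 1e-9))
  means <- tapply(ft$speed, ft$condition, mean)
  expect_gt(means[["movers"]], means[["still"]])
})
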