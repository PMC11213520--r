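# fixtures and independent oracles shared across tests

`%||%` <- function(x, y) if (is.null(x)) y else x

# --- analytic polygons -------------------------------------------------------

make_circle <- function(r = 10, n = 360, centre = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(centre[1] + r * cos(th), centre[2] + r * sin(th))
}

make_ellipse <- function(a = 20, b = 10, n = 360, phi = 0, centre = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ex <- a * cos(th); ey <- b * sin(th)
  cbind(centre[1] + ex * cos(phi) - ey * sin(phi),
        centre[2] + ex * sin(phi) + ey * cos(phi))
}

make_square <- function(side = 10, centre = c(0, 0)) {
  h <- side / 2
  cbind(centre[1] + c(-h, h, h, -h), centre[2] + c(-h, -h, h, h))
}

# non-convex "C" shape: square with a rectangular bite out of the right side
make_c_shape <- function() {
  cbind(
    c(0, 10, 10, 4, 4, 10, 10, 0),
    c(0, 0, 3, 3, 7, 7, 10, 10)
  )
}

# independent shoelace area (cross-check for contours coming out of readers)
polygon_area_for_test <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

# --- toy track tables --------------------------------------------------------

# a track table built from explicit positions; constant circular contour of
# the given area unless contours are supplied
make_track_table <- function(positions, condition = "a", replicate = "r1",
                             local_id = 1, area_um2 = 120, contours = NULL) {
  n <- nrow(positions)
  r <- sqrt(area_um2 / pi)
  contours <- contours %||% lapply(seq_len(n), function(i) {
    make_circle(r, n = 24, centre = c(positions[i, 1], positions[i, 2]))
  })
  tibble::tibble(
    condition = condition, replicate = replicate,
    track_uid = paste(condition, replicate, local_id, sep = "/"),
    frame = seq_len(n) - 1L,
    x_um = positions[, 1], y_um = positions[, 2],
    contour = contours
  )
}

straight_walk <- function(n = 8, step = 2) {
  cbind(seq(0, by = step, length.out = n), rep(0, n))
}

out_and_back_walk <- function(k = 4, step = 2) {
  x <- c(seq(0, by = step, length.out = k + 1),
         seq((k - 1) * step, 0, by = -step))
  cbind(x, rep(0, length(x)))
}

# --- independent edit-distance oracle ---------------------------------------

# plain-R optimal-string-alignment DP over the full matrix; written
# independently of the package's C++ implementation
osa_oracle <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  n <- length(a); m <- length(b)
  if (n == 0) return(m)
  if (m == 0) return(n)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in 1:n) {
    for (j in 1:m) {
      cost <- if (a[i] == b[j]) 0L else 1L
      best <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L, d[i, j] + cost)
      if (i > 1 && j > 1 && a[i] == b[j - 1] && a[i - 1] == b[j]) {
        best <- min(best, d[i - 1, j - 1] + 1L)
      }
      d[i + 1, j + 1] <- best
    }
  }
  d[n + 1, m + 1]
}

# --- planted sequence grammars ----------------------------------------------

# four grammars over a small alphabet; lengths fixed so edit distances are
# dominated by content, not length
make_grammar_sequences <- function(n_per = 30, len = 200, seed = 1) {
  withr::with_seed(seed, {
    seqs <- c(
      lapply(seq_len(n_per), function(i) rep(0L, len)),
      lapply(seq_len(n_per), function(i) as.integer(seq_len(len) %% 2)),
      lapply(seq_len(n_per), function(i) {
        cut <- len %/% 2
        c(rep(0L, cut), rep(1L, len - cut))
      }),
      lapply(seq_len(n_per), function(i) sample(0:2, len, replace = TRUE))
    )
    tibble::tibble(
      track_uid = sprintf("seq%03d", seq_along(seqs)),
      condition = "synthetic",
      sequence = seqs,
      length = lengths(seqs),
      plasticity = vapply(seqs, function(s) sum(diff(s) != 0L), integer(1)),
      grammar = rep(c("constant", "alternating", "block", "random"),
                    each = n_per)
    )
  })
}

# --- planted three-regime experiment ----------------------------------------

# one pure condition per motion regime so the condition label is the
# per-timepoint ground truth; >= 1000 timepoints per regime
three_regime_spec <- function(seed, n_tracks = 25L, len_range = c(45L, 60L)) {
  synthetic_experiment_spec(
    conditions = list(
      stationary = list(regimes = list(regime_stationary()), proportions = 1),
      fast_persistent = list(
        regimes = list(regime_persistent(speed = 6, persistence = 0.95)),
        proportions = 1
      ),
      oscillatory = list(
        regimes = list(regime_oscillatory(speed = 5, run_frames = 4L,
                                          pause_frames = 4L)),
        proportions = 1
      )
    ),
    n_tracks = n_tracks, replicates = "rep1", len_range = len_range,
    seed = seed
  )
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

speed_family <- c("speed", "mean_window_speed", "displacement",
                  "cumulative_length", "euclidean_distance",
                  "max_displacement", "msd")

# metrics excluded when recovering motion regimes: regime identity is
# isotropic (heading-dependent metrics fragment regimes by direction) and
# defined at the window scale (instantaneous metrics are bimodal within an
# oscillatory regime)
regime_recovery_exclusions <- c("turn_angle", "ripley_k", "velocity_x",
                                "velocity_y", "orientation", "speed",
                                "displacement")
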