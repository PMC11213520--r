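# plasticell

Unsupervised analysis of cell behaviour and plasticity in tracked timelapse
microscopy data.

Modern segmentation and tracking tools turn a timelapse movie into thousands
of cell tracks with per-frame outlines. Population averages of single metrics
("mean speed per condition") erase the heterogeneity those data contain: some
cells crawl persistently, some sit still, some oscillate between bursts of
motion and arrest — and single cells switch between these behaviours over
time. plasticell is for experimenters who have tracked-segmentation output
(e.g. from btrack, TrackMate or Usiigaci, organised as
`condition/replicate` folders) and want to know *which* behaviours their
populations contain, in what proportions per condition, and how plastic each
cell is.

## Method

1. **Measure.** Every cell at every timepoint gets a 28-metric vector: 13
   contour morphology metrics (area *A*, perimeter *P*, circularity
   4πA/P², equivalent-ellipse eccentricity/aspect ratio/axes/orientation,
   solidity, extent, …), 13 migration metrics over a trailing time window of
   *W* frames (speed *v* = |Δr|/Δt in µm/min, cumulative length
   *L* = Σ|Δrᵢ|, net displacement *D*, directedness *D/L*, outreach ratio
   maxᵢ|rᵢ−r₁|/L, a windowed MSD scalar, arrest coefficient, …) and 2
   spatial neighbourhood metrics (Ripley's-K-style density, nearest
   neighbour distance). A debris filter first removes tracks shorter than 8
   frames or with median area ≤ 50 µm².
2. **Compare.** Bootstrap effect-size distributions ("plots of difference"):
   the difference of medians between a condition and the control with a 95%
   percentile interval over 1000 within-group resamples, plus per-timepoint
   difference-of-means timeplots and Kruskal–Wallis / Bonferroni-corrected
   rank-sum tests.
3. **Cluster behaviours.** Z-scored metrics → 3-component UMAP → HDBSCAN
   (implemented in this package in C++: mutual-reachability MST, condensed
   hierarchy, excess-of-mass extraction). Every cell-timepoint receives a
   behavioural cluster ID (−1 = unclustered); clusters are summarised by
   silhouette score, density-central exemplar cells and their top
   contributing metrics, and per-condition percentage "fingerprints".
4. **Cluster trajectories.** Each track's cluster-ID sequence is compared to
   every other by normalized Damerau–Levenshtein (optimal string alignment)
   distance, d̂(a,b) = OSA(a,b)/max(|a|,|b|); UMAP on the distance matrix +
   HDBSCAN groups sequences into trajectory IDs. **Plasticity** is the
   number of adjacent-frame cluster switches per cell, compared across
   trajectories and conditions.

A synthetic experiment generator (`simulate_experiment()`) writes
ground-truth-labelled multi-condition track data in the exact h5/CSV formats
the readers consume, so the whole pipeline is testable without microscopy
data.

## Worked example

```r
library(plasticell)

# a two-condition synthetic experiment written to disk as CSV tracks
dir <- tempfile()
simulate_experiment(synthetic_experiment_spec(seed = 1), dir, format = "csv")
cfg <- read_experiment_config(file.path(dir, "config.yaml"))

tracks <- collate_experiment(cfg) |> filter_debris(50, 8)
features <- compute_features(tracks, cfg)

compare_conditions(features, "speed", n_boot = 1000, seed = 1)
#> # A tibble: 1 × 9
#>   metric control test    estimate conf.low conf.high   p_value n_control n_test
#>   <chr>  <chr>   <chr>      <dbl>    <dbl>     <dbl>     <dbl>     <int>  <int>
#> 1 speed  control treated     3.85     3.83      3.86 5.78e-143      2099   2044
```

Cells in the treated condition are a median 3.85 µm/min faster than control
cells, with a 95% bootstrap interval of [3.83, 3.86] µm/min that stays well
clear of zero — a real difference, matching how the treated condition was
simulated (more fast persistent walkers).

```r
clusters <- cluster_behaviours(features, cfg)
glance(clusters)
#> # A tibble: 1 × 5
#>   n_records n_clusters frac_unclustered silhouette space
#>       <int>      <int>            <dbl>      <dbl> <chr>
#> 1      4143          8          0.00217      0.802 embedding

clusters$fingerprint
#> <fingerprint> row percentages (each row sums to 100)
#> # A tibble: 2 × 10
#>   condition   `0`   `1`   `2`   `3`   `4`    `5`   `6`   `7` unclustered
#>   <chr>     <dbl> <dbl> <dbl> <dbl> <dbl>  <dbl> <dbl> <dbl>       <dbl>
#> 1 control    49.2  8.00  8.77   0   19.0  15.1     0    0          0
#> 2 treated    24.7 13.4  15.6   10.5  1.96  0.978  22.8  9.64       0.440

seqs <- behaviour_sequences(clusters) |>
  filter_sequences(cfg$traj_len_min, cfg$traj_len_max)
trajectories <- cluster_trajectories(
  seqs, n_neighbors = cfg$umap_neighbors_traj,
  min_cluster_size = cfg$hdbscan_min_cluster_traj,
  min_samples = cfg$hdbscan_min_samples_traj, seed = cfg$rng_seed)
compare_plasticity(trajectories, by = "condition")$summary
#> # A tibble: 2 × 7
#>   group       n median    q1    q3   min   max
#>   <chr>   <int>  <dbl> <dbl> <dbl> <int> <int>
#> 1 control    40    2.5     0   7.5     0    12
#> 2 treated    40    6.5     2  10       0    14
```

The fingerprint shows the two conditions drawing on a shared behavioural
repertoire in very different proportions (clusters 3, 6 and 7 are nearly
absent from the control, whose cells sit mostly in cluster 0), and treated
cells switch behaviours more than twice as often (median 6.5 vs 2.5
switches per track). `autoplot()` renders each result
(effect-size densities, timeplots with confidence ribbons, UMAP scatters,
fingerprint bars, exemplar contour-and-track graphics); `run_pipeline(cfg)`
executes all stages and exports every table under `results/`, and
`inst/cli/plasticell` wraps the same steps as a shell command
(`plasticell run-all --config config.yaml`).

Numbers above are the output of this example on one machine; cluster counts
and proportions vary with the seed.

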