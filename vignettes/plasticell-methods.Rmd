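---
title: "Morpho-kinetic behavioural clustering and plasticity analysis with plasticell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morpho-kinetic behavioural clustering and plasticity analysis with plasticell}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasticell)
```

# The problem

Timelapse microscopy of migrating cell populations (immune cells crawling on
adhesion ligands being the canonical case) produces thousands of tracked,
segmented cells whose behaviour is heterogeneous and *plastic*: a single cell
may switch between crawling, pausing and exploring within one recording.
Population averages of single metrics wash this structure out. plasticell
takes tracked-segmentation output (not raw images), describes every cell at
every timepoint by a vector of morphology and migration metrics, groups those
per-timepoint descriptions into discrete *behavioural IDs* by density
clustering in a reduced space, converts each track into the categorical
sequence of its behavioural IDs, and groups sequences into *trajectory IDs*
by normalized edit-distance similarity. Plasticity is then simply the number
of adjacent-frame behaviour switches a cell makes.

The pipeline is: load and collate the `condition/replicate` folder tree
(`collate_experiment()`), remove debris (`filter_debris()`), measure
(`compute_features()`), compare conditions (`compare_conditions()`,
`timeplot_difference()`), cluster behaviours (`cluster_behaviours()`), and
cluster behaviour sequences (`behaviour_sequences()`,
`cluster_trajectories()`), with every table exportable as tidy CSV and every
result type drawable via `autoplot()`.

# The metric catalogue

`metric_catalogue()` defines 28 per-cell per-timepoint metrics in three
groups.

**Morphology (13)** comes from the contour polygon alone, in closed form:
area $A$ (shoelace), perimeter $P$, circularity $4\pi A/P^2$, the
second-moment equivalent ellipse (eccentricity
$e=\sqrt{1-\lambda_2/\lambda_1}$, aspect ratio, axis lengths
$4\sqrt{\lambda_i}$, orientation in $(-\pi/2,\pi/2]$), solidity ($A$ over the
convex hull area), extent ($A$ over the bounding-box area), equivalent
diameter $\sqrt{4A/\pi}$, bounding-box and convex areas. Because these are
exact polygon integrals, analytic fixtures (circles, ellipses) give exact
expected values in the tests.

**Migration (13)** is computed over a *trailing* window of $W$ frames ending
at the current frame (default $W=8$; at a 40 s frame interval that is
5.3 min, chosen so one window of typical crawling covers roughly two cell
lengths of path). Over the window positions $r_1..r_m$: instantaneous
displacement and speed $v=|\Delta r|/\Delta t$ (always reported in um/min),
cumulative path length $L=\sum_i|\Delta r_i|$, net displacement
$D=|r_m-r_1|$, directedness (endpoint directionality) $D/L$, outreach ratio
$\max_i |r_i - r_1|/L$, maximum excursion, a scalar MSD (the mean squared
displacement at lag $\lfloor W/2\rfloor$ frames over all in-window pairs),
the turn angle between the last two steps, the arrest coefficient (fraction
of window steps slower than 2 um/min), net x- and y-velocity, and the mean
window speed. Directedness and outreach are 0 when $L=0$ and never exceed 1
(triangle inequality).

**Spatial (2)**: a Ripley's K-style neighbourhood density (neighbours within
50 um divided by the frame's global intensity $N/\text{area}$, no edge
correction) and the nearest-neighbour distance (the frame bounding-box
diagonal serves as the sentinel for a cell alone in its frame, keeping every
record finite).

Choices worth stating explicitly:

* **Trailing windows, clipped at the track start.** Every timepoint of every
  retained track gets a feature vector; partial windows (fewer than $W$
  frames available) are computed on what exists and flagged
  `window_complete = FALSE`. The first frame of a track has no step yet and
  gets zero kinematics.
* **MSD scalarization.** A full MSD-versus-lag curve does not fit in one
  per-timepoint feature; we use the single lag $\lfloor W/2 \rfloor$, which
  balances the number of contributing pairs against the dynamic range of the
  lag. For a Brownian walk with diffusion coefficient $D_c$ the expectation
  is $4 D_c \tau$, which the test suite verifies by simulation.
* **Arrest threshold 2 um/min and Ripley radius 50 um** are configurable
  conventions, roughly one cell diameter per window and a few cell diameters
  of neighbourhood.
* `turn_angle` and `ripley_k` are computed and exported but excluded from
  clustering by default.

# Conditional comparison

Large tracking datasets make p-values uninformative on their own (everything
is "significant" at $n \sim 10^5$ timepoints), so the headline statistic is
an *effect-size distribution*: `bootstrap_effect_size()` resamples each
condition independently with replacement and recomputes the difference of
medians (`n_boot = 1000` by default), reporting the 95% percentile interval.
A distribution clear of zero is evidence of a real difference; crossing zero
indicates statistical inconsequence. Static comparisons use differences of
medians (robust for skewed speed/area distributions); per-timepoint
timeplots use differences of means with a normal-approximation CI for the
group means, and frames where any group has fewer than 5 cells are masked
rather than plotted. The percentile bootstrap (not BCa) was chosen because
it is exactly reproducible under a seed and directly matches the
plots-of-differences visualization. Rank-based testing
(Kruskal--Wallis, then pairwise Wilcoxon rank-sum with Bonferroni
correction) accompanies the intervals via `rank_tests()`.

# Behavioural clustering

`scale_features()` z-scores each included metric (median/IQR scaling is
available; zero-variance columns are dropped with a warning — note that
ellipse-based synthetic contours make `solidity` constant, so it drops on
simulated data). `embed_umap()` produces a 3-component UMAP embedding
(single-threaded, seeded, so runs are bit-identical); `hdbscan()` clusters
the embedding. Clustering the full-dimensional scaled matrix instead is
available via `space = "ndim"`.

The HDBSCAN implementation is part of this package: core distances from the
`min_samples`-th nearest neighbour, mutual-reachability minimum spanning
tree (Prim, distances computed on the fly), condensed hierarchy at
`min_cluster_size`, and excess-of-mass cluster extraction. It reproduces the
labels of the reference implementations on planted-structure data, and the
per-point $\lambda$ (the reciprocal of the distance at which a point
detaches from its cluster) doubles as the density-centrality score that
ranks exemplars. `-1` labels mark unclustered points (low-density or
boundary outliers); they are retained in fingerprints (as their own column
of the row-normalized percentage table) but excluded from silhouettes and
exemplars. By default the hierarchy root is not selectable
(`allow_single_cluster = FALSE`, matching the reference library), except in
trajectory clustering where a behaviourally homogeneous population should
report one trajectory rather than none.

Full-scale defaults (`experiment_config()`): 50 UMAP neighbours,
`min_cluster_size = 500`, `min_samples = 300`, sized for datasets of $10^5$
and more timepoints. Desk-scale synthetic experiments ship their own
proportionate values in the generated `config.yaml` (25 neighbours, 100/25).

Cluster quality is summarised by the mean silhouette over clustered points
(subsampled above 5000 points, seeded). Interpretation of clusters goes
through `top_contributing_metrics()` — metrics ranked by the absolute
difference between the cluster's scaled median and the scaled median of all
other records, a deliberately simple and monotone "maximal variation from
the rest" score — plus exemplar rendering (`plot_exemplar_cell()`) and
per-metric embedding colourings (`metric_heatmap_data()`).

# Trajectory analysis

`behaviour_sequences()` orders each track's cluster IDs by frame (gaps are
bridged by concatenation and counted). Sequences of comparable length
(inclusive bounds, 200--220 frames at full scale) are compared by the
restricted (optimal-string-alignment) Damerau--Levenshtein distance — the
common library variant with substitutions, indels and adjacent
transpositions where no substring is edited twice — normalized by the longer
length, giving $\hat d \in [0,1]$. OSA can violate the triangle inequality;
that is acceptable because UMAP consumes the matrix as a dissimilarity, not
a metric. The normalization denominator $\max(|a|,|b|)$ is the conservative
choice among max/mean/sum (all equivalent up to a monotone factor inside the
narrow length band).

The trajectory layer embeds the precomputed distance matrix with UMAP (2
components, 15 neighbours) and clusters with HDBSCAN (15/10). Unclustered
sequences are excluded from trajectory fingerprints, per-trajectory
plasticity and exemplars, but condition-level plasticity keeps every
sequence, since switching per condition is defined independently of
trajectory membership. Exemplars are medoids (minimum summed normalized
distance to co-members, ties broken by stable record order). Matching
trajectory labels across independently clustered datasets is out of scope:
separate runs live in separate latent spaces.

# The synthetic-data generator

`synthetic_experiment_spec()` / `simulate_experiment()` emulate a
multi-condition, multi-replicate tracked-segmentation experiment in exactly
the input formats the readers consume (the documented minimal h5 schema, or
the generic CSV dialect, written in pixels), with per-track and per-frame
ground-truth labels alongside. Four motion regimes mirror the migratory
phenotypes seen in immune-cell recordings: `stationary` (jitter only),
`brownian` ($\sqrt{2 D \Delta t}$ per-axis steps), `persistent` (heading
noise scaled by $1-\text{persistence}$), and `oscillatory` (alternating
run/pause blocks). Contours are analytic 64-vertex ellipses, optionally
aligned with the velocity, with multiplicative axis jitter; analytic
contours give closed-form morphology oracles, at the cost of constant
solidity. The default experiment is two conditions (a control dominated by
stationary cells versus a treated condition enriched for fast persistent and
oscillatory migration), 2 replicates x 20 tracks of 45--60 frames at 40 s
and 0.5 um/px — roughly 4000 cell-timepoints, so the full pipeline runs in
minutes on one CPU.

What the simulator does *not* emulate: segmentation noise and mask errors,
track breakage and identity switches, cell division, contact interactions,
spatial inhomogeneity of the field, and realistic pixelated contours.
Passing recovery tests therefore demonstrates that the pipeline recovers
planted behavioural structure through the full I/O-features-embedding-
clustering stack — not that real microscopy data will cluster as cleanly.

## Recovery protocols

Two planted-structure experiments anchor the test suite and the acceptance
script. The three-regime experiment (stationary / fast persistent /
oscillatory, one pure condition each, about 1300 timepoints per regime)
must be recovered by HDBSCAN-on-UMAP against regime ground truth. For this
*regime-recovery* clustering the exclusion list is extended beyond the
defaults with the heading-dependent metrics (`velocity_x`, `velocity_y`,
`orientation`) and the instantaneous ones (`speed`, `displacement`): regime
identity is isotropic — two cells crawling east and west are the same
behaviour — and defined at the window scale, whereas instantaneous speed is
legitimately bimodal *within* an oscillatory regime. Without the extended
exclusions the clusters are purer than the regimes (persistent tracks
fragment by heading, oscillatory timepoints split into run and pause),
which is correct per-timepoint behaviour but the wrong target for this
check. The four-grammar sequence experiment (constant, single-phase
alternating, block, uniform-random; 30 sequences of length 200) must yield
four trajectories with the constant trajectory at median plasticity 0 and
the alternating one at 199.

# Numerical and degenerate-input conventions

* Frames are 0-based; geometry is stored in microns immediately at load;
  image coordinates (y down).
* The debris filter applies the area rule to the per-track *median* frame
  area (robust to single-frame segmentation flicker) and is strict:
  exactly 50 um$^2$ does not survive a `> 50` threshold.
* Degenerate contours (under 3 vertices or zero area) are errors, not NAs;
  single-frame tracks get zero kinematics and a note; empty filter results
  are allowed with a warning.
* Zero-length paths define directedness and outreach as 0; two empty
  sequences have normalized distance 0.
* Every stochastic step (bootstrap, UMAP, HDBSCAN-independent subsampling,
  simulation) takes an explicit seed and restores the caller's RNG state;
  fixed seed plus fixed input reproduces every number bit-identically.
* Exemplar and medoid ties break by stable record order.

# Known limitations

* The metric catalogue realizes every named metric of the underlying method
  and fills the remainder with standard morphometrics and kinematics; it is
  configurable, and the exact published set of 28 is not recoverable from
  the primary text.
* Ripley's K has no edge correction (it is excluded from clustering by
  default); the CSR property test uses a field large relative to the radius
  so the uncorrected bias is negligible.
* The h5 reader targets this package's documented minimal schema;
  cross-version compatibility with every btrack release is not guaranteed.
* OSA distances are not metric; trajectory UMAP treats them as
  dissimilarities.
* No hierarchical/donor-level models: replicates are labels, not random
  effects.
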