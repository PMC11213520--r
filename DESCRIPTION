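Package: plasticell
Title: Behavioural Clustering and Plasticity Analysis of Cell Migration Tracks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Unsupervised analysis of tracked cell segmentations from timelapse
    microscopy. Computes a per-cell per-timepoint catalogue of morphology,
    time-windowed migration and spatial-neighbourhood metrics, embeds them with
    UMAP and clusters them with a built-in HDBSCAN implementation into
    behavioural IDs, groups the resulting per-track behaviour sequences into
    trajectory IDs via normalized Damerau-Levenshtein similarity, and
    quantifies behavioural plasticity (cluster switching) and per-condition
    fingerprints with bootstrap effect-size statistics. Includes a synthetic
    track simulator with ground-truth labels, tidy exports, ggplot2 graphics
    and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rhdf5,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    uwot,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
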