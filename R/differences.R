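#' Bootstrap effect size between two samples ("plots of difference")
#'
#' Point estimate is `statistic(test) - statistic(control)` (difference of
#' medians by default; means available for timeplots). The bootstrap resamples
#' each group independently with replacement `n_boot` times and recomputes the
#' difference; the 95% percentile interval of that distribution is reported,
#' alongside a two-sided Wilcoxon rank-sum p-value. An effect-size
#' distribution that does not cross zero is read as evidence of a real
#' difference; crossing zero indicates statistical inconsequence.
#'
#' @param control,test numeric samples (control first, so a positive estimate
#'   means the test condition is larger).
#' @param n_boot number of bootstrap resamples (a warning below 100).
#' @param seed integer seed; the caller's RNG stream is left untouched.
#' @param statistic `"median"` or `"mean"`.
#' @param conf confidence level of the percentile interval.
#' @param names optional `c(control =, test =)` condition labels.
#' @return an `effect_size` object; see [tidy.effect_size()],
#'   [glance.effect_size()] and [autoplot.effect_size()].
#' @examples
#' es <- bootstrap_effect_size(rnorm(100), rnorm(100, 1), n_boot = 200, seed = 1)
#' tidy(es)
#' @export
bootstrap_effect_size <- function(control, test, n_boot = 1000L, seed = NULL,
                                  statistic = c("median", "mean"), conf = 0.95,
                                  names = NULL) {
  statistic <- match.arg(statistic)
  if (length(control) == 0 || length(test) == 0) {
    stop_data("both samples must be non-empty")
  }
  if (n_boot < 100) warn("n_boot < 100: effect-size interval will be unstable")
  stat_fun <- if (statistic == "median") median else mean
  boot_stat <- function(v) {
    m <- matrix(sample(v, length(v) * n_boot, replace = TRUE), ncol = n_boot)
    apply(m, 2, stat_fun)
  }
  boot <- with_local_seed(seed, boot_stat(test) - boot_stat(control))
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(boot, c(alpha, 1 - alpha), type = 7))
  p <- tryCatch(
    suppressWarnings(wilcox.test(test, control)$p.value),
    error = function(e) NA_real_
  )
  structure(list(
    estimate = stat_fun(test) - stat_fun(control),
    boot = boot,
    conf.low = ci[1], conf.high = ci[2], conf = conf,
    statistic = statistic,
    n = c(control = length(control), test = length(test)),
    p_value = p,
    conditions = names %||% c(control = "control", test = "test"),
    seed = seed
  ), class = "effect_size")
}

#' @exportS3Method base::print
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> %s(%s) - %s(%s) = %.4g  [%.4g, %.4g] (%.0f%% percentile bootstrap, n_boot=%d)\n",
              x$statistic, x$conditions[["test"]], x$statistic,
              x$conditions[["control"]], x$estimate, x$conf.low, x$conf.high,
              100 * x$conf, length(x$boot)))
  cat(sprintf("  n = %d vs %d; rank-sum p = %.3g\n",
              x$n[["control"]], x$n[["test"]], x$p_value))
  invisible(x)
}

#' Compare every condition against the control for one metric
#'
#' Data-frame-first wrapper around [bootstrap_effect_size()]: one row per
#' non-control condition, with the difference-of-medians estimate in the
#' metric's units.
#'
#' @param features a `feature_table` (or any tibble with a `condition` column).
#' @param metric metric column name.
#' @param control control condition; defaults to the first condition present.
#' @param n_boot,seed,statistic passed to [bootstrap_effect_size()].
#' @return a tibble with columns `metric`, `control`, `test`, `estimate`,
#'   `conf.low`, `conf.high`, `p_value`, `n_control`, `n_test`; the underlying
#'   `effect_size` objects are attached as attribute `"effect_sizes"`.
#' @export
compare_conditions <- function(features, metric, control = NULL,
                               n_boot = 1000L, seed = NULL,
                               statistic = "median") {
  if (!metric %in% names(features)) {
    stop_data(sprintf("metric '%s' is not a column of the feature table", metric))
  }
  conds <- unique(features$condition)
  control <- control %||% conds[1]
  if (!control %in% conds) {
    stop_data(sprintf("control condition '%s' absent from the data", control))
  }
  a <- features[[metric]][features$condition == control]
  tests <- setdiff(conds, control)
  objs <- lapply(seq_along(tests), function(i) {
    b <- features[[metric]][features$condition == tests[i]]
    bootstrap_effect_size(a, b, n_boot = n_boot,
                          seed = if (is.null(seed)) NULL else seed + i,
                          statistic = statistic,
                          names = c(control = control, test = tests[i]))
  })
  out <- bind_rows(lapply(objs, function(o) tibble(
    metric = metric, control = control, test = o$conditions[["test"]],
    estimate = o$estimate, conf.low = o$conf.low, conf.high = o$conf.high,
    p_value = o$p_value, n_control = o$n[["control"]], n_test = o$n[["test"]]
  )))
  attr(out, "effect_sizes") <- objs
  out
}

#' Per-timepoint condition means, confidence bands and effect sizes
#'
#' For each frame: the per-condition mean with a normal-approximation 95%
#' confidence interval, and for every non-control condition the bootstrap
#' difference-of-means effect size against the control with its percentile
#' interval. Frames where any group involved has fewer than `min_group` cells
#' are masked (`masked = TRUE`, statistics set to `NA`).
#'
#' @param features a `feature_table`.
#' @param metric metric column name.
#' @param control control condition; defaults to the first condition present.
#' @param n_boot bootstrap resamples per frame.
#' @param seed integer seed.
#' @param min_group minimum cells per group per frame.
#' @param conf confidence level.
#' @return a `timeplot_result` tibble: one row per frame x condition with
#'   `mean`, `ci_low`, `ci_high`, `effect`, `effect_low`, `effect_high`
#'   (NA for the control row), `n`, `masked`.
#' @export
timeplot_difference <- function(features, metric, control = NULL,
                                n_boot = 200L, seed = NULL, min_group = 5L,
                                conf = 0.95) {
  if (!metric %in% names(features)) {
    stop_data(sprintf("metric '%s' is not a column of the feature table", metric))
  }
  conds <- unique(features$condition)
  if (length(conds) < 2) stop_data("timeplot_difference needs >= 2 conditions")
  control <- control %||% conds[1]
  if (!control %in% conds) {
    stop_data(sprintf("control condition '%s' absent from the data", control))
  }
  z <- qnorm(1 - (1 - conf) / 2)
  frames <- sort(unique(features$frame))
  rows <- list()
  seed_i <- 0L
  for (f in frames) {
    at <- features[features$frame == f, c("condition", metric)]
    ctrl_v <- at[[metric]][at$condition == control]
    ctrl_ok <- length(ctrl_v) >= min_group
    for (cond in conds) {
      v <- at[[metric]][at$condition == cond]
      ok <- length(v) >= min_group
      half <- if (ok && length(v) > 1) z * sd(v) / sqrt(length(v)) else NA_real_
      eff <- c(NA_real_, NA_real_, NA_real_)
      if (cond != control && ok && ctrl_ok) {
        seed_i <- seed_i + 1L
        es <- bootstrap_effect_size(
          ctrl_v, v, n_boot = n_boot,
          seed = if (is.null(seed)) NULL else seed + seed_i,
          statistic = "mean", conf = conf
        )
        eff <- c(es$estimate, es$conf.low, es$conf.high)
      }
      rows[[length(rows) + 1L]] <- tibble(
        frame = f, condition = cond, n = length(v),
        mean = if (ok) mean(v) else NA_real_,
        ci_low = if (ok) mean(v) - half else NA_real_,
        ci_high = if (ok) mean(v) + half else NA_real_,
        effect = eff[1], effect_low = eff[2], effect_high = eff[3],
        masked = !ok || (cond != control && !ctrl_ok)
      )
    }
  }
  out <- bind_rows(rows)
  out$metric <- metric
  out$control <- control
  structure(out, class = c("timeplot_result", class(out)))
}

#' Rank-based hypothesis tests across condition groups
#'
#' Kruskal--Wallis across all groups; with more than two groups, all pairwise
#' two-sided Wilcoxon rank-sum tests with Bonferroni correction (raw p
#' multiplied by the number of comparisons, capped at 1). If every value in
#' every group is identical the H statistic is undefined and the report is
#' flagged degenerate.
#'
#' @param samples a named list of numeric vectors (one per group), or a data
#'   frame together with `value` and `group` column names.
#' @param value,group column names when `samples` is a data frame.
#' @return a `rank_test_report`: list with `kruskal` (statistic, df, p),
#'   `pairwise` tibble (`group1`, `group2`, `p_raw`, `p_adj`), `n` per group,
#'   `degenerate` flag.
#' @export
rank_tests <- function(samples, value = NULL, group = NULL) {
  if (is.data.frame(samples)) {
    stopifnot(!is.null(value), !is.null(group))
    samples <- split(samples[[value]], samples[[group]])
  }
  if (length(samples) < 2) stop_data("rank_tests needs >= 2 groups")
  if (any(vapply(samples, length, 1L) < 2)) {
    stop_data("every group needs >= 2 observations")
  }
  nm <- names(samples) %||% paste0("group", seq_along(samples))
  values <- unlist(samples, use.names = FALSE)
  degenerate <- length(unique(values)) == 1L
  kw <- if (degenerate) {
    list(statistic = NA_real_, parameter = length(samples) - 1, p.value = NA_real_)
  } else {
    g <- factor(rep(nm, vapply(samples, length, 1L)), levels = nm)
    kruskal.test(values, g)
  }
  combos <- utils::combn(length(samples), 2)
  m <- if (length(samples) > 2) ncol(combos) else 1
  pairwise <- bind_rows(lapply(seq_len(ncol(combos)), function(k) {
    i <- combos[1, k]; j <- combos[2, k]
    p <- tryCatch(
      suppressWarnings(wilcox.test(samples[[i]], samples[[j]])$p.value),
      error = function(e) NA_real_
    )
    tibble(group1 = nm[i], group2 = nm[j], p_raw = p,
           p_adj = pmin(1, p * m))
  }))
  structure(list(
    kruskal = list(statistic = unname(kw$statistic),
                   df = unname(kw$parameter), p_value = unname(kw$p.value)),
    pairwise = pairwise,
    n = setNames(vapply(samples, length, 1L), nm),
    degenerate = degenerate
  ), class = "rank_test_report")
}

#' @exportS3Method base::print
print.rank_test_report <- function(x, ...) {
  if (x$degenerate) {
    cat("<rank_test_report> degenerate: all values identical, H undefined\n")
  } else {
    cat(sprintf("<rank_test_report> Kruskal-Wallis H = %.4g (df = %d), p = %.3g\n",
                x$kruskal$statistic, x$kruskal$df, x$kruskal$p_value))
  }
  cat("  n:", paste(sprintf("%s=%d", names(x$n), x$n), collapse = ", "), "\n")
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}
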