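# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's RNG
# stream. A NULL seed leaves the current stream untouched.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

stop_config <- function(msg) abort(msg, class = "plasticell_config_error")
stop_format <- function(msg) abort(msg, class = "plasticell_format_error")
stop_data <- function(msg) abort(msg, class = "plasticell_data_error")

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_config(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    stop_config(sprintf("`%s` must be > 0 (got %g)", name, x))
  }
  invisible(x)
}

# row-normalized percentage table used by both fingerprint flavours;
# `groups` and `labels` are aligned vectors
build_fingerprint <- function(groups, labels, group_name = "group") {
  stopifnot(length(groups) == length(labels))
  if (length(groups) == 0L) stop_data("cannot fingerprint zero records")
  lab <- ifelse(labels < 0, "unclustered", as.character(labels))
  lvl <- unique(lab)
  num <- suppressWarnings(as.numeric(setdiff(lvl, "unclustered")))
  lvl <- c(as.character(sort(num)), intersect("unclustered", lvl))
  tab <- table(factor(groups), factor(lab, levels = lvl))
  if (any(rowSums(tab) == 0)) {
    empty <- rownames(tab)[rowSums(tab) == 0]
    stop_data(sprintf("group '%s' has no records", empty[1]))
  }
  pct <- sweep(tab, 1, rowSums(tab), "/") * 100
  out <- as_tibble(as.data.frame.matrix(pct), rownames = group_name)
  class(out) <- c("fingerprint", class(out))
  out
}

#' @exportS3Method base::print
print.fingerprint <- function(x, ...) {
  cat("<fingerprint> row percentages (each row sums to 100)\n")
  NextMethod()
}
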