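#' Bootstrap configuration
#'
#' @param n_reps number of bootstrap replicates (default 1000).
#' @param seed integer RNG seed; every resampling stream derives from it.
#' @param ci_level confidence level for percentile intervals (default 0.95).
#' @return list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_reps = 1000L, seed = 1L, ci_level = 0.95) {
  if (n_reps < 1) stop_param("n_reps must be >= 1")
  if (ci_level <= 0 || ci_level >= 1) stop_param("ci_level must be in (0, 1)")
  structure(list(n_reps = as.integer(n_reps), seed = as.integer(seed),
                 ci_level = ci_level),
            class = "bootstrap_config")
}

# Resolve a metric specification into function(pred, gold) -> numeric scalar.
# Built-in names cover the 11-metric panel plus raw confusion counts; a
# function is used as-is.
metric_fun <- function(metric) {
  if (is.function(metric)) return(metric)
  if (!is.character(metric) || length(metric) != 1L) {
    stop_param("metric must be a name or a function(pred, gold)")
  }
  count_fns <- list(
    tp = function(p, g) sum(p == 1 & g == 1),
    fp = function(p, g) sum(p == 1 & g == 0),
    tn = function(p, g) sum(p == 0 & g == 0),
    fn = function(p, g) sum(p == 0 & g == 1)
  )
  if (metric %in% names(count_fns)) return(count_fns[[metric]])
  if (metric %in% metric_names()) {
    return(function(p, g) evaluate(confusion(p, g))[[metric]])
  }
  stop_param("unknown metric '", metric, "'")
}

#' Paired bootstrap confidence interval for a screening metric
#'
#' Nonparametric item-level bootstrap: citations are resampled with
#' replacement, the metric is recomputed on each replicate, and the
#' percentile interval at `ci_level` is reported. Replicates where the metric
#' is undefined (NaN — e.g. no gold positives drawn for a sensitivity) are
#' dropped and counted; infinite values (e.g. a likelihood ratio with zero
#' false positives) are legitimate and retained, so an interval such as
#' \code{[46.6, Inf]} can be reported. A warning is emitted when more than 1%
#' of replicates are dropped.
#'
#' @param items data frame with a binary `gold` column and one binary
#'   prediction column per rater.
#' @param metric a metric name (one of [metric_names()], or `"tp"`, `"fp"`,
#'   `"tn"`, `"fn"`) or a `function(pred, gold)` returning a scalar.
#' @param rater name of the prediction column to evaluate.
#' @param config a [bootstrap_config()].
#' @return Object of class `bootstrap_result`: list with `point`, `ci_low`,
#'   `ci_high`, `p_value` (NULL here; see [bootstrap_compare()]),
#'   `n_reps_used`, `n_dropped`, and the replicate vector in `replicates`.
#' @examples
#' items <- fixture_from_counts(confusion_counts(20, 10, 60, 10))
#' bootstrap_ci(items, "sensitivity", "pred", bootstrap_config(200, seed = 7))
#' @export
bootstrap_ci <- function(items, metric, rater, config = bootstrap_config()) {
  stopifnot(inherits(config, "bootstrap_config"))
  f <- metric_fun(metric)
  gold <- items$gold
  pred <- items[[rater]]
  if (is.null(pred)) stop_param("rater column '", rater, "' not found")
  point <- f(pred, gold)
  if (is.na(point)) stop_data("metric undefined on the full sample")

  n <- length(gold)
  reps <- withr::with_seed(config$seed, {
    vapply(seq_len(config$n_reps), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      f(pred[idx], gold[idx])
    }, numeric(1))
  })
  finish_bootstrap(point, reps, config)
}

#' Paired bootstrap comparison of a metric between two raters
#'
#' Both raters are evaluated on the *same* resampled items in every
#' replicate, so the within-item correlation between raters is preserved.
#' The replicate statistic is metric(a) - metric(b); the CI is the percentile
#' interval of that difference and the two-tailed p-value is the sign-share
#' construction 2 * min(share of replicates <= 0, share >= 0), floored at
#' 1/n_reps (a Monte-Carlo p-value of exactly zero is never reported).
#'
#' @inheritParams bootstrap_ci
#' @param rater_a,rater_b prediction column names to compare.
#' @return `bootstrap_result` for the difference, with `p_value` set.
#' @examples
#' items <- fixture_from_counts(confusion_counts(20, 10, 60, 10))
#' items$other <- items$gold
#' bootstrap_compare(items, "sensitivity", "other", "pred",
#'                   bootstrap_config(200, seed = 7))
#' @export
bootstrap_compare <- function(items, metric, rater_a, rater_b,
                              config = bootstrap_config()) {
  stopifnot(inherits(config, "bootstrap_config"))
  f <- metric_fun(metric)
  gold <- items$gold
  pa <- items[[rater_a]]; pb <- items[[rater_b]]
  if (is.null(pa)) stop_param("rater column '", rater_a, "' not found")
  if (is.null(pb)) stop_param("rater column '", rater_b, "' not found")
  point <- f(pa, gold) - f(pb, gold)
  if (is.na(point)) stop_data("metric undefined on the full sample")

  n <- length(gold)
  reps <- withr::with_seed(config$seed, {
    vapply(seq_len(config$n_reps), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      f(pa[idx], gold[idx]) - f(pb[idx], gold[idx])
    }, numeric(1))
  })
  res <- finish_bootstrap(point, reps, config)
  used <- res$replicates
  p <- 2 * min(mean(used <= 0), mean(used >= 0))
  res$p_value <- min(1, max(1 / config$n_reps, p))
  res
}

finish_bootstrap <- function(point, reps, config) {
  keep <- !is.na(reps) # NaN replicates undefined; +/-Inf retained
  n_dropped <- sum(!keep)
  if (n_dropped > 0.01 * config$n_reps) {
    warning(sprintf("%d of %d bootstrap replicates undefined and dropped",
                    n_dropped, config$n_reps))
  }
  used <- reps[keep]
  if (!length(used)) stop_data("all bootstrap replicates undefined")
  alpha <- (1 - config$ci_level) / 2
  ci <- quantile(used, c(alpha, 1 - alpha), names = FALSE)
  structure(
    list(point = point, ci_low = ci[1], ci_high = ci[2], p_value = NULL,
         n_reps_used = length(used), n_dropped = n_dropped,
         replicates = used),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap: point %.4g, CI [%.4g, %.4g] (%d replicates",
              x$point, x$ci_low, x$ci_high, x$n_reps_used))
  if (x$n_dropped > 0) cat(sprintf(", %d dropped", x$n_dropped))
  cat(")")
  if (!is.null(x$p_value)) cat(sprintf(", two-tailed p = %.4g", x$p_value))
  cat("\n")
  invisible(x)
}
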