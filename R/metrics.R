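#' Confusion counts against a gold standard
#'
#' Cross-tabulates binary predictions against binary gold-standard labels.
#' Items with a missing prediction are excluded from the counts and reported
#' in the `n_missing` field, so every metric downstream has an explicit
#' denominator.
#'
#' @param pred binary (0/1) prediction vector; NA allowed (masked item).
#' @param gold binary (0/1) gold-standard vector, same length, no NA.
#' @return An object of class `confusion_counts`: a list with integer fields
#'   `tp`, `fp`, `tn`, `fn` and `n_missing`.
#' @examples
#' confusion(c(1, 0, 1, 0), c(1, 0, 0, 1))
#' @seealso [evaluate()], [confusion_counts()]
#' @export
confusion <- function(pred, gold) {
  check_aligned(pred, gold, "pred", "gold")
  check_binary(gold, "gold")
  check_binary(pred, "pred", allow_na = TRUE)
  keep <- !is.na(pred)
  p <- as.integer(pred[keep])
  g <- as.integer(gold[keep])
  confusion_counts(
    tp = sum(p == 1L & g == 1L),
    fp = sum(p == 1L & g == 0L),
    tn = sum(p == 0L & g == 0L),
    fn = sum(p == 0L & g == 1L),
    n_missing = sum(!keep)
  )
}

#' Construct confusion counts directly
#'
#' @param tp,fp,tn,fn non-negative counts of true positives, false positives,
#'   true negatives and false negatives.
#' @param n_missing number of items excluded for missing predictions.
#' @return `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fp, tn, fn, n_missing = 0L) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop_data("confusion counts must be non-negative integers")
  }
  structure(
    list(tp = as.integer(tp), fp = as.integer(fp), tn = as.integer(tn),
         fn = as.integer(fn), n_missing = as.integer(n_missing)),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("Confusion counts (N = %d): TP %d, FP %d, TN %d, FN %d",
              x$tp + x$fp + x$tn + x$fn, x$tp, x$fp, x$tn, x$fn))
  if (x$n_missing > 0) cat(sprintf("  [%d masked]", x$n_missing))
  cat("\n")
  invisible(x)
}

# Ratio with the documented sentinels: positive/0 -> Inf, 0/0 -> NaN.
# An already-undefined numerator (NaN from an upstream 0/0) stays NaN.
safe_ratio <- function(num, den) {
  if (is.nan(num) || is.nan(den)) return(NaN)
  if (den == 0) {
    if (num == 0) NaN else Inf
  } else {
    num / den
  }
}

#' The screening-evaluation metric panel
#'
#' Computes the eleven diagnostic metrics used to compare screeners against a
#' gold standard. With counts TP/FP/TN/FN (N their sum):
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN), PLR = sensitivity/(1-specificity),
#' NLR = (1-sensitivity)/specificity, balanced accuracy =
#' (sensitivity+specificity)/2, Jaccard = TP/(TP+FP+FN),
#' FNR = FN/(TP+FN), proportion missed = FN/(FN+TN) — the share of truly
#' relevant records among those a rater discards — and workload saving =
#' TN/N, the fraction of the corpus correctly auto-excluded (human effort
#' avoided).
#'
#' Undefined ratios carry sentinels rather than erroring: a positive
#' numerator over a zero denominator is `Inf` (the convention for PLR with
#' perfect specificity), `0/0` is `NaN`.
#'
#' @param counts a `confusion_counts` object with N > 0.
#' @return Object of class `metric_report`: a named list of the 11 raw metric
#'   values plus the input counts. Use [metric_row()] with `digits = 2` for
#'   the conventional 2-decimal rendering; printing rounds half-up likewise.
#' @examples
#' evaluate(confusion_counts(tp = 140, fp = 366, tn = 684, fn = 8))
#' @export
evaluate <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  if (n == 0) stop_data("cannot evaluate empty confusion counts (N = 0)")

  sens <- safe_ratio(tp, tp + fn)
  spec <- safe_ratio(tn, tn + fp)
  metrics <- list(
    sensitivity        = sens,
    specificity        = spec,
    ppv                = safe_ratio(tp, tp + fp),
    npv                = safe_ratio(tn, tn + fn),
    plr                = safe_ratio(sens, 1 - spec),
    nlr                = safe_ratio(1 - sens, spec),
    balanced_accuracy  = (sens + spec) / 2,
    jaccard            = safe_ratio(tp, tp + fp + fn),
    fnr                = safe_ratio(fn, tp + fn),
    proportion_missed  = safe_ratio(fn, fn + tn),
    workload_saving    = tn / n
  )
  structure(c(metrics, list(counts = counts, n = n)), class = "metric_report")
}

#' Names of the metrics in a metric report, in conventional row order
#' @return character vector of the 11 metric names.
#' @export
metric_names <- function() {
  c("sensitivity", "specificity", "ppv", "npv", "plr", "nlr",
    "balanced_accuracy", "jaccard", "fnr", "proportion_missed",
    "workload_saving")
}

#' @export
print.metric_report <- function(x, digits = 2, ...) {
  cat(sprintf("Screening metric panel (N = %d):\n", x$n))
  for (m in metric_names()) {
    v <- x[[m]]
    shown <- if (is.infinite(v)) "∞" else
      formatC(round_half_up(v, digits), format = "f", digits = digits)
    cat(sprintf("  %-18s %s\n", m, shown))
  }
  invisible(x)
}

#' Extract the metric panel as a one-row tibble
#'
#' @param report a `metric_report`.
#' @param digits optional rounding (half-up); `NULL` keeps raw values.
#' @return one-row tibble with the 11 metric columns.
#' @export
metric_row <- function(report, digits = NULL) {
  stopifnot(inherits(report, "metric_report"))
  vals <- vapply(metric_names(), function(m) report[[m]], numeric(1))
  if (!is.null(digits)) {
    finite <- is.finite(vals)
    vals[finite] <- round_half_up(vals[finite], digits)
  }
  tibble::as_tibble(as.list(vals))
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e), where p_o is
#' the observed proportion of agreeing items and p_e the agreement expected
#' from the two raters' marginal inclusion rates. Symmetric in its arguments
#' and invariant to relabeling the two categories in both vectors at once.
#'
#' When both raters are constant and identical (p_e = 1) kappa is undefined;
#' `NA` is returned with a warning rather than an error.
#'
#' @param a,b aligned binary (0/1) vectors. Items where either is NA are
#'   dropped.
#' @return Object of class `kappa_result`: list with `kappa`, `p_o`, `p_e`,
#'   `n` (items used), and `ci` (NULL unless filled by a bootstrap).
#' @examples
#' cohen_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0))
#' @export
cohen_kappa <- function(a, b) {
  check_aligned(a, b, "a", "b")
  check_binary(a, "a", allow_na = TRUE)
  check_binary(b, "b", allow_na = TRUE)
  keep <- !is.na(a) & !is.na(b)
  a <- as.integer(a[keep]); b <- as.integer(b[keep])
  n <- length(a)
  if (n == 0) stop_data("no complete pairs for kappa")
  p_o <- mean(a == b)
  pa <- mean(a); pb <- mean(b)
  p_e <- pa * pb + (1 - pa) * (1 - pb)
  kap <- if (p_e == 1) {
    warning("kappa undefined: both raters constant and identical")
    NA_real_
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  structure(list(kappa = kap, p_o = p_o, p_e = p_e, n = n, ci = NULL),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %.3f (p_o = %.3f, p_e = %.3f, n = %d)\n",
              x$kappa, x$p_o, x$p_e, x$n))
  if (!is.null(x$ci)) cat(sprintf("  95%% CI [%.3f, %.3f]\n", x$ci[1], x$ci[2]))
  invisible(x)
}

#' Pairwise kappa matrix over a decision matrix
#'
#' @param decisions items-by-raters data frame or matrix of binary decisions
#'   (rater columns; an optional `id` column is ignored).
#' @return tibble with columns `rater`, `versus`, `kappa`, `n` — one row per
#'   unordered rater pair, in column order.
#' @export
kappa_matrix <- function(decisions) {
  decisions <- as.data.frame(decisions)
  decisions$id <- NULL
  raters <- names(decisions)
  if (length(raters) < 2) stop_param("need at least 2 raters")
  pairs <- utils::combn(raters, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    k <- cohen_kappa(decisions[[pairs[1, j]]], decisions[[pairs[2, j]]])
    tibble::tibble(rater = pairs[1, j], versus = pairs[2, j],
                   kappa = k$kappa, n = k$n)
  })
  do.call(rbind, rows)
}

#' Mean kappa between one rater and the others
#'
#' The headline agreement figure for an AI screener is the mean of its
#' pairwise kappas against every human rater. `pairs = "all"` instead
#' averages every pairwise kappa in the matrix.
#'
#' @param decisions items-by-raters binary data frame.
#' @param rater name of the focal rater column (ignored for `pairs = "all"`).
#' @param pairs `"versus_rater"` (default) or `"all"`.
#' @return single numeric mean kappa.
#' @export
mean_kappa <- function(decisions, rater, pairs = c("versus_rater", "all")) {
  pairs <- match.arg(pairs)
  km <- kappa_matrix(decisions)
  if (pairs == "all") return(mean(km$kappa))
  sel <- km$rater == rater | km$versus == rater
  if (!any(sel)) stop_param("rater '", rater, "' not found in decisions")
  mean(km$kappa[sel])
}
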