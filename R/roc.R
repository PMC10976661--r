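#' Binarize ordinal ratings at a threshold
#'
#' An item is predicted "include" when its rating is at or above the
#' threshold (e.g. threshold 3 includes ratings 3, 4 and 5).
#'
#' @param ratings integer vector of ratings in 1..5 (NA allowed, preserved).
#' @param threshold integer cutoff in 1..5.
#' @return integer 0/1 vector, NA where the rating is missing.
#' @examples
#' binarize(c(1, 2, 3, 4, 5), 3)
#' @export
binarize <- function(ratings, threshold) {
  check_rating_scale(ratings)
  if (length(threshold) != 1L || !threshold %in% 1:5) {
    stop_param("threshold must be a single integer in 1..5")
  }
  as.integer(ratings >= threshold)
}

check_rating_scale <- function(ratings) {
  bad <- !is.na(ratings) & !(ratings %in% 1:5)
  if (any(bad)) {
    stop_data("ratings must be integers in 1..5; offending value ",
              ratings[bad][1])
  }
  invisible(ratings)
}

#' Tie-aware AUC of ordinal ratings against a binary gold standard
#'
#' The probability that a randomly chosen gold-positive item receives a
#' higher rating than a randomly chosen gold-negative item, with rating ties
#' credited 1/2 (the midrank / Mann-Whitney convention). On a discrete 1-5
#' scale this equals the trapezoidal area under the empirical ROC curve
#' through the five threshold operating points.
#'
#' @param ratings integer ratings 1..5 (NA dropped, with the gold label, and
#'   counted).
#' @param gold aligned binary gold vector containing both classes.
#' @return single numeric AUC in \code{[0, 1]}.
#' @examples
#' rating_auc(c(5, 4, 2, 1), c(1, 1, 0, 0))
#' @export
rating_auc <- function(ratings, gold) {
  check_aligned(ratings, gold, "ratings", "gold")
  check_rating_scale(ratings)
  check_binary(gold, "gold")
  keep <- !is.na(ratings)
  r <- ratings[keep]; g <- as.integer(gold[keep])
  n_pos <- sum(g == 1L); n_neg <- sum(g == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop_data("gold standard must contain both classes (",
              n_pos, " positives, ", n_neg, " negatives)")
  }
  rk <- rank(r) # midranks handle ties
  (sum(rk[g == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC over the 1-5 rating scale with Youden-optimal threshold
#'
#' Evaluates every threshold t in 1..5 (include iff rating >= t), computes
#' Youden's J(t) = sensitivity(t) + specificity(t) - 1, and selects the
#' threshold maximizing J. Ties in J are broken toward the *highest* tied
#' threshold: in screening triage a higher cutoff excludes more records and
#' saves more human workload at equal J.
#'
#' @inheritParams rating_auc
#' @return Object of class `roc_result`:
#'   * `points` — tibble `threshold`, `sensitivity`, `fpr` (1-specificity),
#'     ordered by threshold; endpoints (0,0)/(1,1) are *not* rows, they are
#'     implicit curve anchors used by the AUC;
#'   * `auc` — tie-aware AUC;
#'   * `youden_j` — named numeric, J at thresholds 1..5;
#'   * `optimal_threshold`, `optimal_j`;
#'   * `n_missing` — ratings dropped as NA.
#' @examples
#' set.seed(1)
#' g <- rbinom(200, 1, 0.2)
#' r <- pmin(5, pmax(1, 3 + g + sample(-1:1, 200, TRUE)))
#' youden_roc(r, g)
#' @export
youden_roc <- function(ratings, gold) {
  check_aligned(ratings, gold, "ratings", "gold")
  check_rating_scale(ratings)
  check_binary(gold, "gold")
  keep <- !is.na(ratings)
  n_missing <- sum(!keep)
  r <- ratings[keep]; g <- as.integer(gold[keep])
  n_pos <- sum(g == 1L); n_neg <- sum(g == 0L)
  if (n_pos == 0 || n_neg == 0) {
    stop_data("gold standard must contain both classes")
  }

  thresholds <- 1:5
  sens <- vapply(thresholds, function(t) sum(r >= t & g == 1L) / n_pos,
                 numeric(1))
  spec <- vapply(thresholds, function(t) sum(r < t & g == 0L) / n_neg,
                 numeric(1))
  j <- sens + spec - 1
  names(j) <- paste0(">=", thresholds)
  best_j <- max(j)
  # highest threshold among ties
  optimal <- max(thresholds[j >= best_j - 1e-12])

  structure(
    list(
      points = tibble::tibble(threshold = thresholds, sensitivity = sens,
                              fpr = 1 - spec),
      auc = rating_auc(r, g),
      youden_j = j,
      optimal_threshold = optimal,
      optimal_j = best_j,
      n_missing = n_missing
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("Ordinal ROC: AUC %.3f, Youden-optimal threshold >= %d (J = %.3f)\n",
              x$auc, x$optimal_threshold, x$optimal_j))
  print(x$points)
  invisible(x)
}
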