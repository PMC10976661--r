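#' Expand confusion counts into an item-level fixture
#'
#' Emits one row per counted item — TP (gold 1, pred 1), then FN (1, 0), then
#' FP (0, 1), then TN (0, 0) — so that `confusion(fixture$pred, fixture$gold)`
#' round-trips to the input counts exactly. The gold-descending /
#' prediction-descending order and sequential ids make fixtures diff-stable.
#'
#' @param counts a `confusion_counts` object.
#' @return tibble with columns `id`, `gold`, `pred`.
#' @examples
#' fixture_from_counts(confusion_counts(tp = 2, fp = 1, tn = 3, fn = 1))
#' @export
fixture_from_counts <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  gold <- c(rep(1L, counts$tp), rep(1L, counts$fn),
            rep(0L, counts$fp), rep(0L, counts$tn))
  pred <- c(rep(1L, counts$tp), rep(0L, counts$fn),
            rep(1L, counts$fp), rep(0L, counts$tn))
  tibble::tibble(
    id = sprintf("item%05d", seq_len(length(gold))),
    gold = gold, pred = pred
  )
}

#' Expand cumulative threshold counts into an item-level rating fixture
#'
#' Printed screening reports often tabulate, for each rating threshold t in
#' 2..5, the cumulative true-positive and false-positive counts (items rated
#' >= t in each gold class). Successive differencing recovers the per-rating
#' class counts — the rating-1 count is the class total minus the count at
#' >= 2 — and this function emits an item table that reproduces every
#' cumulative count on re-thresholding.
#'
#' @param cum data frame with columns `threshold` (a subset of 2:5), `tp`
#'   (gold-positives rated >= threshold) and `fp` (gold-negatives rated >=
#'   threshold); both columns must be non-increasing in threshold and bounded
#'   by the class totals.
#' @param n_pos,n_neg gold class totals.
#' @return tibble with columns `id`, `gold`, `rating` (gold-descending, then
#'   rating-descending, sequential ids).
#' @examples
#' cum <- data.frame(threshold = 2:5, tp = c(141, 140, 107, 15),
#'                   fp = c(486, 366, 138, 13))
#' fx <- ratings_fixture_from_cumulative(cum, n_pos = 148, n_neg = 1050)
#' confusion(binarize(fx$rating, 3), fx$gold)
#' @export
ratings_fixture_from_cumulative <- function(cum, n_pos, n_neg) {
  cum <- as.data.frame(cum)
  stopifnot(all(c("threshold", "tp", "fp") %in% names(cum)))
  if (!all(cum$threshold %in% 2:5) || anyDuplicated(cum$threshold)) {
    stop_data("thresholds must be distinct values in 2..5")
  }
  cum <- cum[order(cum$threshold), ]

  # cumulative counts at all thresholds 1..5; >=1 is the class total and
  # thresholds absent from the input inherit the next lower stated count
  expand <- function(col, total) {
    full <- setNames(rep(NA_real_, 5), 1:5)
    full["1"] <- total
    full[as.character(cum$threshold)] <- cum[[col]]
    for (t in 2:5) if (is.na(full[t])) full[t] <- full[t - 1]
    full
  }
  ctp <- expand("tp", n_pos)
  cfp <- expand("fp", n_neg)
  if (any(diff(ctp) > 0) || any(diff(cfp) > 0)) {
    stop_data("cumulative counts must be non-increasing in threshold")
  }
  if (any(ctp > n_pos) || any(cfp > n_neg) || any(ctp < 0) || any(cfp < 0)) {
    stop_data("cumulative counts exceed class totals or are negative")
  }

  per_pos <- as.integer(c(-diff(ctp), ctp[5]))  # counts for ratings 1..5
  per_neg <- as.integer(c(-diff(cfp), cfp[5]))

  gold <- c(rep(1L, n_pos), rep(0L, n_neg))
  rating <- c(rep(5:1, times = rev(per_pos)), rep(5:1, times = rev(per_neg)))
  n <- length(gold)
  tibble::tibble(id = sprintf("item%05d", seq_len(n)), gold = gold,
                 rating = rating)
}

#' A binary rater's operating point
#'
#' @param name rater label.
#' @param sensitivity,specificity probabilities in \code{[0, 1]}.
#' @return list of class `rater_profile`.
#' @export
rater_profile <- function(name, sensitivity, specificity) {
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 || specificity > 1) {
    stop_param("sensitivity and specificity must lie in [0, 1]")
  }
  structure(list(name = name, sensitivity = sensitivity,
                 specificity = specificity),
            class = "rater_profile")
}

#' Specification of a simulated multi-rater screening study
#'
#' The default emulates a 1198-citation radiology screening study: ~12%
#' relevance prevalence (148/1198), three general-physician raters at the
#' operating points such a study reports, two near-concordant expert raters,
#' and one ordinal 1-5 AI-style rater whose latent-score calibration makes
#' its thresholded operating points resemble the published cut-off table
#' (see [study_cumulative_counts()]).
#'
#' Raters are coupled through a one-factor probit model: each item carries a
#' shared standard-normal difficulty, mixed into every rater's latent decision
#' variable with weight `sqrt(correlation)`, which makes pairwise kappa
#' tunable independently of the marginal operating points.
#'
#' @param n_items number of citations.
#' @param prevalence gold-positive rate in (0, 1).
#' @param raters list of [rater_profile()]s.
#' @param correlation shared-latent coupling in \code{[0, 1)}.
#' @param ordinal_rater list with `cuts` (4 strictly increasing thresholds on
#'   the latent score), `mean_pos`, `sd_pos`, `mean_neg`, `sd_neg`
#'   (class-conditional latent distributions).
#' @param seed integer RNG seed.
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(n_items = 1198L,
                            prevalence = 148 / 1198,
                            raters = default_rater_profiles(),
                            correlation = 0.5,
                            ordinal_rater = default_ordinal_rater(),
                            seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1) stop_param("prevalence must be in (0, 1)")
  if (correlation < 0 || correlation >= 1) stop_param("correlation must be in [0, 1)")
  if (is.unsorted(ordinal_rater$cuts, strictly = TRUE) ||
      length(ordinal_rater$cuts) != 4L) {
    stop_param("ordinal_rater$cuts must be 4 strictly increasing values")
  }
  stopifnot(all(vapply(raters, inherits, logical(1), "rater_profile")))
  structure(
    list(n_items = as.integer(n_items), prevalence = prevalence,
         raters = raters, correlation = correlation,
         ordinal_rater = ordinal_rater, seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

#' Default binary rater profiles for the simulated study
#'
#' Three GP-level screeners at published operating points (0.55/0.94,
#' 0.55/0.99, 0.74/0.94) and two synthetic expert-level screeners; the
#' experts' operating points are invented (a study whose experts *define*
#' the gold standard never reports them) and chosen high.
#'
#' @return list of [rater_profile()]s.
#' @export
default_rater_profiles <- function() {
  list(
    rater_profile("gp1", 0.55, 0.94),
    rater_profile("gp2", 0.55, 0.99),
    rater_profile("gp3", 0.74, 0.94),
    rater_profile("expert1", 0.90, 0.98),
    rater_profile("expert2", 0.85, 0.98)
  )
}

#' Default ordinal AI-rater calibration
#'
#' Cut-points and class-conditional latent distributions obtained by
#' probit-inverting the per-rating class proportions reconstructed from the
#' published cumulative cut-off counts: with the negative class anchored at
#' N(0,1) the four cuts are the probit of its cumulative proportions, and the
#' positive-class mean/sd solve the >= 3 and >= 4 operating points exactly
#' (the >= 2 and >= 5 points are approximated).
#'
#' @return list with `cuts`, `mean_pos`, `sd_pos`, `mean_neg`, `sd_neg`.
#' @export
default_ordinal_rater <- function() {
  list(cuts = c(0.093, 0.389, 1.119, 2.245),
       mean_pos = 1.545, sd_pos = 0.72,
       mean_neg = 0, sd_neg = 1)
}

#' Simulate a multi-rater screening study
#'
#' Gold labels are Bernoulli(prevalence). Each binary rater includes an item
#' when its latent variable `sqrt(rho) * u_item + sqrt(1-rho) * noise` falls
#' below the probit of its class-conditional accuracy (sensitivity on
#' gold-positives, 1 - specificity on gold-negatives), so marginal operating
#' points match the profiles exactly while the shared difficulty `u_item`
#' induces positive pairwise agreement. The ordinal rater's rating is 1 plus
#' the number of cut-points below its class-conditional latent score, which
#' shares the same item difficulty.
#'
#' @param spec a [simulation_spec()].
#' @return list with
#'   * `decisions` — tibble `id`, `gold`, one 0/1 column per binary rater;
#'   * `ratings` — tibble `id`, `rating` (the ordinal rater);
#'   * `spec` — the spec used.
#' @examples
#' sim <- simulate_study(simulation_spec(n_items = 300, seed = 42))
#' head(sim$decisions)
#' @export
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, {
    n <- spec$n_items
    gold <- rbinom(n, 1L, spec$prevalence)
    u <- rnorm(n) # shared item difficulty
    w <- sqrt(spec$correlation)
    v <- sqrt(1 - spec$correlation)

    decisions <- tibble::tibble(id = sprintf("item%05d", seq_len(n)),
                                gold = gold)
    for (rp in spec$raters) {
      latent <- w * u + v * rnorm(n)
      # include iff latent below the class-conditional probit cutoff
      cut <- ifelse(gold == 1L, qnorm(rp$sensitivity),
                    qnorm(1 - rp$specificity))
      decisions[[rp$name]] <- as.integer(latent < cut)
    }

    orc <- spec$ordinal_rater
    z <- w * u * -1 + v * rnorm(n) # difficulty lowers the relevance score
    score <- ifelse(gold == 1L, orc$mean_pos + orc$sd_pos * z,
                    orc$mean_neg + orc$sd_neg * z)
    rating <- 1L + as.integer(rowSums(outer(score, orc$cuts, `>`)))
    ratings <- tibble::tibble(id = decisions$id, rating = rating)

    list(decisions = decisions, ratings = ratings, spec = spec)
  })
}

#' Write a simulated study to CSV files
#'
#' Emits `corpus.csv` (templated placeholder titles/abstracts sufficient for
#' the mock backend), `decisions.csv` (long format `id,rater,decision`),
#' `ratings.csv` and `gold.csv` under `dir`.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_simulated_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dec <- sim$decisions
  raters <- setdiff(names(dec), c("id", "gold"))
  long <- do.call(rbind, lapply(raters, function(r) {
    data.frame(id = dec$id, rater = r, decision = dec[[r]])
  }))
  corpus <- tibble::tibble(
    id = dec$id,
    title = sprintf("Simulated citation %s (%s)", dec$id,
                    ifelse(dec$gold == 1, "diagnostic accuracy imaging study",
                           "unrelated report")),
    abstract = ifelse(
      dec$gold == 1,
      "Placeholder abstract about diagnostic accuracy of imaging in the target population.",
      "Placeholder abstract on an unrelated topic."),
    ref_type = "JOUR", pub_year = 2022L, topic = "SIMULATED",
    source_db = "synthetic"
  )
  paths <- file.path(dir, c("corpus.csv", "decisions.csv", "ratings.csv",
                            "gold.csv"))
  write.csv(corpus, paths[1], row.names = FALSE)
  write.csv(long, paths[2], row.names = FALSE)
  write.csv(sim$ratings, paths[3], row.names = FALSE)
  write.csv(dec[, c("id", "gold")], paths[4], row.names = FALSE)
  invisible(paths)
}
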