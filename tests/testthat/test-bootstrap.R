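test_that("bootstrap streams are seed-deterministic", {
  items <- fixture_from_counts(confusion_counts(30, 20, 120, 30))
  b1 <- bootstrap_ci(items, "sensitivity", "pred", bootstrap_config(200, 9))
  b2 <- bootstrap_ci(items, "sensitivity", "pred", bootstrap_config(200, 9))
  expect_identical(b1$replicates, b2$replicates)
  b3 <- bootstrap_ci(items, "sensitivity", "pred", bootstrap_config(200, 10))
  expect_false(identical(b1$replicates, b3$replicates))
})

test_that("a constant metric yields a zero-width interval", {
  items <- fixture_from_counts(confusion_counts(40, 0, 0, 0))
  # on an all-positive gold with an all-include rater, sensitivity is 1
  bs <- bootstrap_ci(items, "sensitivity", "pred", bootstrap_config(100, 1))
  expect_equal(bs$ci_low, 1)
  expect_equal(bs$ci_high, 1)
})

test_that("comparing a rater with itself gives zero difference and p = 1", {
  items <- fixture_from_counts(confusion_counts(25, 15, 80, 20))
  items$again <- items$pred
  cmp <- bootstrap_compare(items, "sensitivity", "pred", "again",
                           bootstrap_config(300, 2))
  expect_equal(cmp$point, 0)
  expect_equal(cmp$p_value, 1)
  expect_true(all(cmp$replicates == 0))
})

test_that("a strictly dominant rater hits the Monte-Carlo p-value floor", {
  items <- fixture_from_counts(confusion_counts(30, 0, 150, 20))
  items$oracle <- items$gold       # perfect rater
  items$never <- 0L                # constant exclude
  cmp <- bootstrap_compare(items, "sensitivity", "oracle", "never",
                           bootstrap_config(500, 3))
  expect_equal(cmp$p_value, 1 / 500)
  expect_true(cmp$ci_low > 0)
})

test_that("swapping raters negates the CI and preserves the p-value", {
  set.seed(801)
  gold <- rbinom(300, 1, 0.3)
  items <- tibble::tibble(
    id = seq_len(300), gold = gold,
    a = ifelse(gold == 1, rbinom(300, 1, 0.9), rbinom(300, 1, 0.1)),
    b = ifelse(gold == 1, rbinom(300, 1, 0.7), rbinom(300, 1, 0.1))
  )
  cfg <- bootstrap_config(400, 4)
  ab <- bootstrap_compare(items, "sensitivity", "a", "b", cfg)
  ba <- bootstrap_compare(items, "sensitivity", "b", "a", cfg)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(ab$ci_low, -ba$ci_high)
  expect_equal(ab$ci_high, -ba$ci_low)
})

test_that("percentile CI matches the boot package on the same statistic", {
  skip_if_not_installed("boot")
  items <- fixture_from_counts(confusion_counts(35, 25, 100, 25))
  cfg <- bootstrap_config(2000, 12)
  ours <- bootstrap_ci(items, "sensitivity", "pred", cfg)
  stat <- function(d, idx) {
    g <- d$gold[idx]; p <- d$pred[idx]
    sum(p & g) / sum(g)
  }
  set.seed(12)
  bt <- boot::boot(items, stat, R = 2000)
  bci <- boot::boot.ci(bt, type = "perc")$percent[4:5]
  # two independent resampling streams: agreement within Monte-Carlo error
  expect_equal(ours$ci_low, bci[1], tolerance = 0.02)
  expect_equal(ours$ci_high, bci[2], tolerance = 0.02)
})

test_that("percentile bounds approach the normal interval as reps grow", {
  # binomial-style metric at large n: percentile ~ Wald interval
  items <- fixture_from_counts(confusion_counts(1600, 0, 0, 400))
  bs <- bootstrap_ci(items, "sensitivity", "pred", bootstrap_config(4000, 21))
  p_hat <- 0.8
  se <- sqrt(p_hat * (1 - p_hat) / 2000)
  expect_lt(abs(bs$ci_low - (p_hat - 1.96 * se)), 0.004)
  expect_lt(abs(bs$ci_high - (p_hat + 1.96 * se)), 0.004)
})

test_that("undefined replicates are dropped with a count, not imputed", {
  # tiny sample with a single gold positive: many replicates draw none
  items <- fixture_from_counts(confusion_counts(1, 2, 5, 0))
  expect_warning(
    bs <- bootstrap_ci(items, "sensitivity", "pred", bootstrap_config(400, 5)),
    "dropped")
  expect_gt(bs$n_dropped, 0)
  expect_equal(bs$n_reps_used + bs$n_dropped, 400)
  expect_false(anyNA(bs$replicates))
})

test_that("likelihood-ratio intervals may be right-infinite, never NA", {
  # near-perfect specificity: replicates with zero FPs give PLR = Inf
  items <- fixture_from_counts(confusion_counts(47, 3, 1047, 101))
  bs <- bootstrap_ci(items, "plr", "pred", bootstrap_config(400, 6))
  expect_true(is.finite(bs$ci_low))
  expect_gt(bs$ci_high, bs$ci_low)
  expect_false(anyNA(bs$replicates))
})

test_that("a large true sensitivity gap is detected in nearly every run", {
  # paired design, true gap 0.3 at the study's scale: p < 0.001 expected
  n <- 1198
  detected <- vapply(1:20, function(s) {
    set.seed(9000 + s)
    gold <- rbinom(n, 1, 148 / 1198)
    items <- tibble::tibble(
      id = seq_len(n), gold = gold,
      a = ifelse(gold == 1, rbinom(n, 1, 0.95), rbinom(n, 1, 0.35)),
      b = ifelse(gold == 1, rbinom(n, 1, 0.65), rbinom(n, 1, 0.05))
    )
    cmp <- bootstrap_compare(items, "sensitivity", "a", "b",
                             bootstrap_config(1000, 9000 + s))
    cmp$p_value <= 0.001 # the Monte-Carlo floor 1/B at B = 1000
  }, logical(1))
  expect_gte(mean(detected), 0.95)
})

test_that("bootstrap errors when the metric is undefined on the full sample", {
  items <- fixture_from_counts(confusion_counts(0, 3, 10, 0)) # no positives
  expect_error(bootstrap_ci(items, "sensitivity", "pred",
                            bootstrap_config(50, 1)),
               class = "screeneval_data_error")
  expect_error(bootstrap_ci(items, "tp", "nosuch", bootstrap_config(50, 1)),
               class = "screeneval_param_error")
})
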