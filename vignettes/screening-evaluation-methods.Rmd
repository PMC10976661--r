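---
title: "Methods: evaluating an LLM screener against human raters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating an LLM screener against human raters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screeneval)
```

## The problem

Title/abstract screening is the bottleneck of systematic reviewing: thousands
of candidate citations must each be judged against an eligibility frame
(PICOS: Population, Intervention, Comparison, Outcomes, Study design), and a
single missed relevant study damages the review more than many false
inclusions. `screeneval` evaluates a screener — human or LLM — against an
expert-adjudicated gold standard, with the statistical machinery such an
evaluation needs: the diagnostic-accuracy metric panel, chance-corrected
agreement, ordinal ROC analysis with threshold selection, and paired
bootstrap inference. A synthetic-data module generates every input the
pipeline consumes, so the whole package runs offline and its behaviour is
testable end to end.

The package ships the printed summary counts of a published evaluation of a
GPT-3.5-class rater screening 1198 radiology abstracts (148 relevant by the
expert gold standard, ~12% prevalence) as packaged reference data
(`study_rater_counts()`, `study_cumulative_counts()`, `study_topic_counts()`);
`reproduce_tables()` pushes those counts through the package's own
computations and regenerates the study's summary tables.

## Metric panel

All metrics derive from the confusion counts TP/FP/TN/FN of a binary
prediction against the gold standard (`confusion()`, `evaluate()`):
sensitivity TP/(TP+FN), specificity TN/(TN+FP), PPV, NPV, the likelihood
ratios PLR = sens/(1−spec) and NLR = (1−sens)/spec, balanced accuracy
(sens+spec)/2, Jaccard TP/(TP+FP+FN), and three screening-specific figures:

* **FNR** = FN/(TP+FN) — relevant studies wrongly discarded, as a share of
  all relevant studies;
* **proportion missed** = FN/(FN+TN) — relevant studies among those the
  rater predicts irrelevant (equals 1 − NPV);
* **workload saving** = TN/N — the share of the corpus correctly
  auto-excluded, i.e. the human reading avoided.

Three identities (FNR = 1 − sensitivity, proportion missed = 1 − NPV,
balanced accuracy = the sens/spec mean) hold exactly pre-rounding and are
enforced as property tests. Undefined ratios carry sentinels rather than
errors: positive/0 is `Inf` (a likelihood-ratio interval can legitimately be
right-infinite), 0/0 is `NaN`. Rendered tables round half-up to 2 decimals
(`round_half_up()`), matching how such panels are conventionally printed;
raw values are always kept.

Items with a missing prediction are excluded from the counts and surfaced in
`n_missing` — metrics never silently change denominator.

## Agreement

`cohen_kappa()` implements κ = (p_o − p_e)/(1 − p_e) with p_e from the two
raters' marginals. When both raters are constant and identical, p_e = 1 and
κ is undefined; we return `NA` with a warning rather than erroring, since a
screening matrix column can degenerate this way. The headline "mean kappa"
for an AI rater is ambiguous when several pair sets exist; `mean_kappa()`
defaults to the mean of the AI-versus-each-human pairwise kappas (the
reading under which the reference study's five AI rows average to its quoted
0.27) and offers `pairs = "all"` as the alternative.

## Consensus and adjudication

`consensus()` implements the three standard multi-reviewer rules: sensitive
(any includes), specific (all include), voting (strict majority). The
inclusion sets nest — specific ⊆ voting ⊆ sensitive — so against any fixed
gold standard, sensitivity is ordered sensitive ≥ voting ≥ specific and
specificity the reverse; both orderings are property-tested. Two open points
were decided as follows: a voting tie with an even rater count resolves to
*include* (screening favours sensitivity; the three-rater study never hits
this case), and masked decisions drop the item from the consensus with a
logged count rather than counting as "exclude", which would bias the
specific rule. `adjudicate()` forms the gold standard: agreements copy the
experts' shared value; disagreements defer to the third expert.

## Ordinal ROC and threshold choice

The AI rater produces ordinal 1–5 relevance ratings; `binarize(r, t)`
includes at rating ≥ t. `rating_auc()` is the tie-aware rank statistic: the
probability a random gold-positive outranks a random gold-negative with ties
credited ½ — on a 5-point scale this coincides with the trapezoidal area
under the empirical ROC through the five thresholds, which is why a single
implementation serves both readings (the suite cross-checks it against
pROC). `youden_roc()` evaluates J(t) = sens(t) + spec(t) − 1 at t = 1..5 and
picks the argmax; ties resolve to the **highest** tied threshold, the choice
that excludes more records at equal J. The threshold map covers 1..5; the
(0,0)/(1,1) endpoints are implicit curve anchors only. Missing ratings are
dropped with a logged count.

On the packaged cumulative counts this machinery yields AUC 0.8638 (0.86 at
2 dp) and optimal threshold ≥ 3 — computed, not transcribed; the per-rating
class distributions (positives 7/1/33/92/15, negatives 564/120/228/125/13)
are recovered by successively differencing the cumulative TP/FP columns.

## Paired bootstrap

`bootstrap_ci()` resamples *citations* with replacement (B = 1000 by
default) and reports the percentile interval; `bootstrap_compare()` computes
metric(a) − metric(b) per replicate **on the same resampled items**, so the
within-item correlation between raters is respected — the design that makes
difference p-values meaningful for paired raters. Choices made where
convention offers several options:

* percentile CI (2.5/97.5) rather than BCa — the simplest method consistent
  with printed count intervals; swap-in alternatives are deliberately easy;
* two-tailed p = 2·min(share of replicate differences ≤ 0, share ≥ 0),
  clamped to [1/B, 1]: a Monte-Carlo p of exactly 0 is never reported, so at
  B = 1000 the smallest attainable p is 0.001;
* replicates where the metric is undefined (NaN — e.g. a resample with no
  gold positives) are dropped and counted, with a warning above 1%;
  infinite replicate values are retained (a PLR interval may end at ∞);
* the full replicate stream derives from one seed (`bootstrap_config()`), so
  identical configs give identical results, and the swap-symmetry
  p(a,b) = p(b,a) holds exactly.

A calibration check (analysis/04, mirrored in the test suite) simulates 200
raters of known sensitivity 0.74 at n = 500 items, prevalence 0.3, B = 1000:
the nominal 95% percentile CI covered the truth in 93% of runs, within the
91–99% acceptance band — percentile intervals for binomial-type metrics
undercover slightly at this n, which is expected behaviour, not a defect.

## The rating harness

`build_prompt()` renders a versioned template (`inst/prompts/default-v1.txt`)
with four blocks in fixed order — role, task (explain *then* rate, answer in
JSON), article (title, abstract, reference type, year), PICOS. The wording
is this package's paraphrase of the standard role/task/article/PICOS
screening prompt; alternative templates can be added as new files and A/B'd
by name. A missing abstract renders an explicit `[no abstract available]`
marker rather than an empty block. `parse_response()` tolerates prose around
the JSON, scans for balanced objects with a string-aware bracket matcher,
and takes the first object carrying a `rating` key; a rating outside 1..5 is
a validation error that `screen_corpus()` retries up to `max_retries` times
before recording the item as missing (missing ratings propagate as missing —
never imputed). The backend contract is a plain function from prompt text to
reply text; the shipped `mock_backend()` rates by keyword overlap between
the article and PICOS blocks, is fully deterministic, and is the only
backend the test suite exercises. A live chat-completion backend satisfies
the same contract but is intentionally outside the tests: no network, no
nondeterminism in CI.

`triage()` implements two-stage screening: auto-exclude below `low`,
auto-include at/above `high`, human review between — the hybrid design in
which the model clears the bulk of clearly irrelevant records and humans
concentrate on the indeterminate band (ratings 2–4 under the defaults).

## Corpus handling

`read_corpus()`/`write_corpus()` speak CSV (fixed documented header) and a
minimal RIS dialect (TY/TI/AB/PY plus ID/KW/DB/DO, continuation lines); no
maintained R RIS parser exists, so the reader is hand-written and
round-trip-tested. `filter_corpus()` deduplicates by DOI when both records
carry one, else by normalized title (lowercased, punctuation and whitespace
collapsed) + publication year — an EndNote-style rule; first occurrence
wins, then records with whitespace-only abstracts are dropped, and the log
satisfies n_final = n_input − duplicates − missing. `sample_per_topic()`
draws up to 200 records per topic (topics smaller than that are taken
whole), with one generator seeded once and topics processed in sorted order
for cross-platform reproducibility. The packaged per-topic table is
internally consistent: each final count equals total − duplicates − missing,
and the per-topic samples min(200, final) sum to exactly 1198 — the
200-per-topic design with one undersized topic (198) accounts for the whole
corpus.

## Synthetic data: what it emulates and what it does not

`fixture_from_counts()` and `ratings_fixture_from_cumulative()` are exact:
they expand printed confusion/cumulative counts into item tables whose
re-evaluation reproduces the counts identically (round-trip property tests).
They carry no text — items are ids and labels.

`simulate_study()` generates a correlated multi-rater study under a
one-factor probit model: each item has a shared standard-normal difficulty
u; rater j includes the item when √ρ·u + √(1−ρ)·ε falls below the probit of
its class-conditional accuracy, so the *marginal* operating points equal the
profile exactly (parameter-recovery tested at n = 10⁵ within 3 SE) while ρ
tunes agreement independently. The ordinal rater shares the same difficulty
(sign-flipped, so harder items score lower) through class-conditional latent
Gaussians cut at four thresholds.

Defaults mirror the reference study's shape: n = 1198, prevalence 148/1198,
GP profiles at the published operating points (0.55/0.94, 0.55/0.99,
0.74/0.94), and two **synthetic** expert profiles (0.90/0.98, 0.85/0.98) —
the study never prints individual expert operating points, since the experts
define its gold standard. The ordinal calibration was derived by
probit-inversion of the reconstructed class distributions: anchoring the
negative class at N(0,1) gives cuts (0.093, 0.389, 1.119, 2.245) from its
cumulative proportions, and solving the ≥3 and ≥4 positive-class operating
points gives N(1.545, 0.72²); the ≥2 and ≥5 points are then approximate by
construction — a two-parameter class cannot match four cutoffs. With
coupling ρ = 0.5, simulated pairwise kappas land in the published 0.4–0.8
human range with AI-vs-human kappas around 0.2–0.3; this is qualitative
emulation — no correlation parameter is published to target.

What the simulation does **not** emulate: real abstract text (titles and
abstracts are templated placeholders, sufficient for the mock backend, not
for any linguistic claim), rater drift over time, per-topic heterogeneity in
prevalence or difficulty, and any property of a live LLM backend. Passing
tests therefore certify the statistical machinery, not the behaviour of a
particular model on real citations.

## Problem sizes used by the tests

The suite favours exact fixtures (the 1198-item expansions) where the check
is deterministic, and keeps stochastic checks at sizes chosen for stable
verdicts: parameter recovery at n = 10⁴–10⁵, coupling monotonicity over 40
seeds at n = 1500, the bootstrap coverage study at 200 × B = 1000 on n = 500,
and the end-to-end pipeline tests at n = 250 with B = 80 — sizes at which
every assertion sits several standard errors from its pass boundary.

## Known limitations

* The bootstrap p-value construction (sign-share with floor) is one
  defensible convention among several; published two-tailed bootstrap
  p-values computed differently will agree in magnitude class, not digit.
* No multiple-testing correction is applied across a metric-panel grid of
  p-values, mirroring common practice in these evaluations; treat the grid
  descriptively.
* Percentile CIs slightly undercover for extreme proportions at small n;
  BCa would improve this at the cost of comparability with printed
  count intervals.
* The RIS dialect covers the tags the pipeline uses; exotic vendor tags are
  ignored on read and therefore not preserved on rewrite.
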