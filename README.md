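# screeneval

Evaluating LLM-assisted title/abstract screening against human raters.

Systematic reviews begin with screening thousands of citations against a
PICOS eligibility frame (Population, Intervention, Comparison, Outcomes,
Study design). An LLM that rates each abstract's relevance on an ordinal 1–5
scale can clear the bulk of clearly irrelevant records — if its error
profile is understood. `screeneval` provides the full evaluation stack for
that question, for methodologists and review teams comparing automated
screeners with human reviewers:

* **Corpus handling** — RIS/CSV ingest, DOI/normalized-title deduplication,
  missing-abstract filtering, seeded per-topic sampling.
* **Rating harness** — role/task/article/PICOS prompt assembly, pluggable
  backends (`function(prompt) -> reply`), JSON explain-then-rate parsing
  with retries, a deterministic keyword-overlap mock, two-stage triage.
* **Consensus** — sensitive / specific / voting rules over multiple binary
  raters; third-expert adjudication into a gold standard.
* **Metrics** — confusion counts and the 11-metric panel: sensitivity,
  specificity, PPV, NPV, PLR, NLR, balanced accuracy, Jaccard, and the
  screening-specific FNR = FN/(TP+FN), proportion missed = FN/(FN+TN), and
  workload saving = TN/N; Cohen's κ = (p₀ − pₑ)/(1 − pₑ) for agreement.
* **Ordinal ROC** — tie-aware AUC (midrank/Mann–Whitney convention) over the
  1–5 scale and Youden-optimal threshold J(t) = sens(t) + spec(t) − 1.
* **Paired bootstrap** — item-level percentile CIs and two-tailed sign-share
  p-values for metric differences, both raters evaluated on the same
  resampled items.
* **Synthetic data** — exact item-level expansion of printed confusion /
  cumulative counts, and a one-factor probit simulator of correlated
  multi-rater studies with an ordinal AI-style rater.

The package also carries, as packaged reference data, the printed summary
counts of a published evaluation of a GPT-3.5-class screener on 1198
radiology abstracts (148 relevant per the expert gold standard), so the
study's tables can be regenerated from counts by computation.

## Worked example

Expand the reference study's AI-rater counts at its optimal cutoff and
evaluate the panel:

```r
library(screeneval)

rep <- evaluate(confusion_counts(tp = 140, fp = 366, tn = 684, fn = 8))
print(rep)
#> Screening metric panel (N = 1198):
#>   sensitivity        0.95
#>   specificity        0.65
#>   ppv                0.28
#>   npv                0.99
#>   plr                2.71
#>   nlr                0.08
#>   balanced_accuracy  0.80
#>   jaccard            0.27
#>   fnr                0.05
#>   proportion_missed  0.01
#>   workload_saving    0.57
```

Read: the AI rater recovers 95% of relevant citations (missing only
8 of 148), would let a team safely skip reading 57% of the corpus, but
includes liberally (specificity 0.65, PPV 0.28) — the profile of a
first-stage filter, not a replacement reviewer.

ROC and threshold selection from the cumulative cut-off counts:

```r
fx <- ratings_fixture_from_cumulative(study_cumulative_counts(),
                                      n_pos = 148, n_neg = 1050)
roc <- youden_roc(fx$rating, fx$gold)
roc$auc                 #> 0.8638256  (0.86 at 2 dp)
roc$optimal_threshold   #> 3          (include at rating >= 3)
```

Bootstrap interval for the sensitivity on the same items:

```r
items <- fixture_from_counts(confusion_counts(140, 366, 684, 8))
bootstrap_ci(items, "sensitivity", "pred", bootstrap_config(1000, seed = 17))
#> Bootstrap: point 0.9459, CI [0.9091, 0.9784] (1000 replicates)
```

A fully simulated study end to end — corpus, five human raters, ordinal AI
rater, consensus, kappa matrix, metric panels, triage:

```r
bundle <- run_pipeline(run_config(spec = simulation_spec(seed = 1)))
bundle$roc$optimal_threshold
subset(bundle$metric_panel, metric == "sensitivity")
```

## Analysis scripts

Thin drivers under `analysis/` narrate the standard workflow and write
their tables under `results/`:

1. `01_reproduce_published_tables.R` — metric panels, threshold table and
   ROC summary regenerated from the packaged counts.
2. `02_bootstrap_intervals.R` — B = 1000 percentile CIs for the AI rater's
   counts and metrics.
3. `03_simulated_study.R` — the full pipeline on a simulated 1198-citation
   study with expert-adjudicated gold standard.
4. `04_coverage_and_calibration.R` — CI coverage, generator
   parameter-recovery, and kappa-vs-coupling checks.

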