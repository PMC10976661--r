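Package: screeneval
Title: Evaluating LLM-Assisted Abstract Screening Against Human Raters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating large-language-model raters against human
    reviewers in systematic-review title/abstract screening. Provides citation
    corpus handling (RIS/CSV ingest, deduplication, per-topic sampling), a
    prompt/response rating harness with pluggable backends and a deterministic
    mock, multi-rater consensus rules and third-expert adjudication, the full
    diagnostic-accuracy metric panel (sensitivity, specificity, predictive
    values, likelihood ratios, balanced accuracy, Jaccard, false-negative rate,
    proportion missed, workload saving) with Cohen's kappa, ordinal-rating ROC
    with tie-aware AUC and Youden threshold selection, paired nonparametric
    bootstrap confidence intervals and two-tailed p-values, two-stage triage,
    and a synthetic-data module that expands printed confusion counts into
    item-level fixtures and simulates correlated multi-rater screening studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    withr
Suggests:
    boot,
    e1071,
    pROC,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
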