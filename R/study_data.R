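# Packaged reference counts from a published evaluation of an LLM screening
# 1198 radiology abstracts against an expert-adjudicated gold standard
# (148 relevant, 1050 irrelevant). Stored as code so the reproduction
# workflow and the acceptance checks need no external input.

#' Gold-standard class totals of the reference screening study
#'
#' @return named list with `n_pos` (relevant citations) and `n_neg`.
#' @export
study_gold_totals <- function() {
  list(n_pos = 148L, n_neg = 1050L)
}

#' Cumulative cut-off counts of the reference study's AI rater
#'
#' For each rating threshold t in 2..5, the number of gold-positive (`tp`)
#' and gold-negative (`fp`) citations the AI rater scored at or above t.
#' Together with [study_gold_totals()] these determine the full per-rating
#' class distributions (see [ratings_fixture_from_cumulative()]).
#'
#' @return tibble with columns `threshold`, `tp`, `fp`.
#' @export
study_cumulative_counts <- function() {
  tibble::tibble(
    threshold = 2:5,
    tp = c(141L, 140L, 107L, 15L),
    fp = c(486L, 366L, 138L, 13L)
  )
}

#' Confusion counts of the reference study's raters and consensuses
#'
#' TP/TN/FP/FN of each human rater, each GP consensus, and the AI rater at
#' its Youden-optimal threshold (>= 3), all against the expert-adjudicated
#' gold standard.
#'
#' @return tibble with columns `rater`, `tp`, `tn`, `fp`, `fn`.
#' @export
study_rater_counts <- function() {
  tibble::tribble(
    ~rater,                 ~tp,  ~tn,  ~fp, ~fn,
    "ai_ge3",              140L, 684L, 366L,   8L,
    "gp1",                  82L, 990L,  60L,  66L,
    "gp2",                  81L, 1037L, 13L,  67L,
    "gp3",                 109L, 982L,  68L,  39L,
    "voting_consensus",     92L, 1031L, 19L,  56L,
    "specific_consensus",   47L, 1047L,  3L, 101L,
    "sensitive_consensus", 133L,  931L, 119L, 15L
  )
}

#' Per-topic corpus filtering summary of the reference study
#'
#' Search yield, duplicates, missing-abstract removals and final corpus size
#' per topic, with the fraction a 200-citation sample covers.
#'
#' @return tibble with columns `topic`, `total_found`, `duplicates`,
#'   `missing_abstracts`, `final`, `sample_proportion`.
#' @export
study_topic_counts <- function() {
  tibble::tribble(
    ~topic,       ~total_found, ~duplicates, ~missing_abstracts, ~final, ~sample_proportion,
    "COLORECTAL",        3263L,       1564L,               338L,  1361L, 0.147,
    "PAD",                307L,         74L,                35L,    198L, 1.000,
    "DVT",              21802L,       7164L,              1509L, 13129L, 0.015,
    "PET",                831L,        234L,                25L,    572L, 0.350,
    "SPECT",             2533L,        812L,               198L,  1523L, 0.131,
    "STENT",              768L,        206L,                69L,    493L, 0.406
  )
}
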