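# End-to-end orchestration over a simulated (or supplied) study and
# reproduction of the published-count tables.

#' Pipeline run configuration
#'
#' @param spec a [simulation_spec()] describing the study to generate.
#' @param gold_definition which gold standard to evaluate against:
#'   `"expert_adjudicated"` (the two expert raters adjudicated by a third;
#'   in a simulated study the simulation truth stands in for the third
#'   expert), or a consensus rule over the GP raters (`"sensitive"`,
#'   `"specific"`, `"voting"`), or `"truth"` (the simulated labels).
#' @param low,high triage thresholds (see [triage()]).
#' @param boot a [bootstrap_config()]; its seed drives all resampling.
#' @param comparator rater against which pairwise metric p-values are
#'   computed (default the thresholded AI rater).
#' @return list of class `run_config`.
#' @export
run_config <- function(spec = simulation_spec(),
                       gold_definition = c("expert_adjudicated", "sensitive",
                                           "specific", "voting", "truth"),
                       low = 2L, high = 5L,
                       boot = bootstrap_config(n_reps = 1000L,
                                               seed = spec$seed),
                       comparator = "ai") {
  gold_definition <- match.arg(gold_definition)
  structure(list(spec = spec, gold_definition = gold_definition,
                 low = as.integer(low), high = as.integer(high),
                 boot = boot, comparator = comparator),
            class = "run_config")
}

#' Run the full screening-evaluation pipeline on a simulated study
#'
#' Simulates the study, forms the configured gold standard, thresholds the
#' ordinal AI rater at its Youden-optimal cutoff, and produces the standard
#' report bundle: a pairwise kappa table, an 11-metric panel per rater with
#' bootstrap CIs and two-tailed p-values against the comparator, the
#' threshold-wise confusion table for the AI rater, the ROC summary, and
#' triage counts. Deterministic for a fixed configuration.
#'
#' @param config a [run_config()].
#' @param ci_metrics metrics to bootstrap (default the full panel; trim to
#'   speed up exploratory runs).
#' @return list of class `report_bundle` with elements `kappa_table`,
#'   `metric_panel`, `threshold_table`, `roc`, `triage_counts`, `items`,
#'   `log`.
#' @export
run_pipeline <- function(config = run_config(),
                         ci_metrics = metric_names()) {
  stopifnot(inherits(config, "run_config"))
  sim <- simulate_study(config$spec)
  dec <- sim$decisions
  rater_names <- setdiff(names(dec), c("id", "gold"))
  gp_raters <- grep("^gp", rater_names, value = TRUE)
  expert_raters <- grep("^expert", rater_names, value = TRUE)

  gold <- switch(config$gold_definition,
    truth = dec$gold,
    expert_adjudicated = {
      if (length(expert_raters) < 2) {
        stop_param("expert_adjudicated gold needs two expert raters")
      }
      adjudicate(dec[[expert_raters[1]]], dec[[expert_raters[2]]],
                 tiebreaker = dec$gold)$gold
    },
    consensus(dec[, gp_raters], rule = config$gold_definition)
  )
  if (length(unique(gold)) < 2) stop_data("gold standard is single-class")

  roc <- youden_roc(sim$ratings$rating, gold)
  ai <- binarize(sim$ratings$rating, roc$optimal_threshold)

  items <- tibble::tibble(id = dec$id, gold = gold)
  for (r in rater_names) items[[r]] <- dec[[r]]
  items[["ai"]] <- ai
  for (rule in c("voting", "specific", "sensitive")) {
    items[[paste0(rule, "_consensus")]] <-
      as.integer(consensus(dec[, gp_raters], rule = rule))
  }

  all_raters <- setdiff(names(items), c("id", "gold"))
  kappa_table <- kappa_matrix(items[, c(rater_names, "ai")])

  panel <- do.call(rbind, lapply(all_raters, function(r) {
    rep_full <- evaluate(confusion(items[[r]], gold))
    rows <- lapply(ci_metrics, function(m) {
      bs <- bootstrap_ci(items, m, r, config$boot)
      p <- if (r != config$comparator) {
        bootstrap_compare(items, m, r, config$comparator, config$boot)$p_value
      } else {
        NA_real_
      }
      tibble::tibble(rater = r, metric = m, value = rep_full[[m]],
                     ci_low = bs$ci_low, ci_high = bs$ci_high, p_value = p)
    })
    do.call(rbind, rows)
  }))

  threshold_table <- do.call(rbind, lapply(1:5, function(t) {
    cc <- confusion(binarize(sim$ratings$rating, t), gold)
    tibble::tibble(threshold = t, tp = cc$tp, tn = cc$tn, fp = cc$fp,
                   fn = cc$fn)
  }))

  tri <- triage(sim$ratings$rating, config$low, config$high)
  triage_counts <- as.list(table(tri))

  structure(
    list(
      kappa_table = kappa_table,
      metric_panel = panel,
      threshold_table = threshold_table,
      roc = list(auc = roc$auc, youden_j = as.list(roc$youden_j),
                 optimal_threshold = roc$optimal_threshold,
                 points = roc$points),
      triage_counts = triage_counts,
      items = items,
      log = list(seed = config$spec$seed, n_items = config$spec$n_items,
                 gold_definition = config$gold_definition,
                 bootstrap_reps = config$boot$n_reps,
                 package_version = as.character(utils::packageVersion("screeneval")))
    ),
    class = "report_bundle"
  )
}

#' Write a report bundle as machine-readable JSON (plus CSV tables)
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the JSON path.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(bundle$kappa_table, file.path(dir, "kappa_table.csv"),
            row.names = FALSE)
  write.csv(bundle$metric_panel, file.path(dir, "metric_panel.csv"),
            row.names = FALSE)
  write.csv(bundle$threshold_table, file.path(dir, "threshold_table.csv"),
            row.names = FALSE)
  json_path <- file.path(dir, "report_bundle.json")
  payload <- list(
    kappa_table = bundle$kappa_table,
    metric_panel = bundle$metric_panel,
    threshold_table = bundle$threshold_table,
    roc = list(auc = bundle$roc$auc,
               youden_j = bundle$roc$youden_j,
               optimal_threshold = bundle$roc$optimal_threshold),
    triage_counts = bundle$triage_counts,
    log = bundle$log
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(json_path)
}

#' Reproduce the published summary tables from packaged counts
#'
#' Expands the packaged reference-study counts ([study_rater_counts()],
#' [study_cumulative_counts()]) through the package's own metric, ROC and
#' threshold machinery — no printed metric value is copied — and returns the
#' three standard tables.
#'
#' @param digits rounding (half-up) applied to the rendered metric panel;
#'   raw values are kept in the `value` column.
#' @return list with
#'   * `metric_panel` — tibble: one row per (rater, metric) with raw and
#'     rounded values;
#'   * `threshold_table` — tibble of TP/TN/FP/FN at each AI rating cutoff;
#'   * `roc` — list: tie-aware `auc` (raw and rounded), per-threshold Youden
#'     J, `optimal_threshold`.
#' @export
reproduce_tables <- function(digits = 2) {
  counts <- study_rater_counts()
  panel <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    cc <- confusion_counts(tp = counts$tp[i], fp = counts$fp[i],
                           tn = counts$tn[i], fn = counts$fn[i])
    rep <- evaluate(cc)
    vals <- vapply(metric_names(), function(m) rep[[m]], numeric(1))
    tibble::tibble(rater = counts$rater[i], metric = metric_names(),
                   value = vals,
                   rounded = ifelse(is.finite(vals),
                                    round_half_up(vals, digits), vals))
  }))

  totals <- study_gold_totals()
  cum <- study_cumulative_counts()
  threshold_table <- tibble::tibble(
    threshold = cum$threshold,
    tp = cum$tp,
    tn = totals$n_neg - cum$fp,
    fp = cum$fp,
    fn = totals$n_pos - cum$tp
  )

  fx <- ratings_fixture_from_cumulative(cum, totals$n_pos, totals$n_neg)
  roc <- youden_roc(fx$rating, fx$gold)

  list(
    metric_panel = panel,
    threshold_table = threshold_table,
    roc = list(auc = roc$auc, auc_rounded = round_half_up(roc$auc, digits),
               youden_j = roc$youden_j,
               optimal_threshold = roc$optimal_threshold)
  )
}
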