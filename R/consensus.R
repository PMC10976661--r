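#' Consensus decision over multiple binary raters
#'
#' Combines the columns of an items-by-raters decision matrix into one
#' include/exclude vector under one of three rules:
#' * `sensitive` — include if at least one rater includes;
#' * `specific`  — include only if every rater includes;
#' * `voting`    — include if a strict majority includes; with an even rater
#'   count an exact tie resolves to *include* (screening favours sensitivity).
#'
#' Items where any rater's decision is masked (NA) get an NA consensus and
#' are counted in the `n_masked` attribute rather than silently treated as
#' exclusions.
#'
#' @param decisions data frame or matrix, one binary column per rater (at
#'   least two); an `id` column, if present, is ignored.
#' @param rule one of `"sensitive"`, `"specific"`, `"voting"`.
#' @return integer 0/1/NA vector, one entry per item, with attribute
#'   `n_masked`.
#' @examples
#' m <- data.frame(r1 = c(1, 1, 0), r2 = c(0, 1, 0), r3 = c(0, 1, 1))
#' consensus(m, "sensitive")
#' consensus(m, "voting")
#' @export
consensus <- function(decisions, rule = c("sensitive", "specific", "voting")) {
  rule <- match.arg(rule)
  decisions <- as.data.frame(decisions)
  decisions$id <- NULL
  if (ncol(decisions) < 2) stop_param("consensus needs at least 2 raters")
  for (nm in names(decisions)) check_binary(decisions[[nm]], nm, allow_na = TRUE)

  m <- as.matrix(decisions)
  masked <- apply(m, 1, anyNA)
  out <- rep(NA_integer_, nrow(m))
  rows <- which(!masked)
  if (length(rows)) {
    inc <- rowSums(m[rows, , drop = FALSE])
    k <- ncol(m)
    out[rows] <- switch(rule,
      sensitive = as.integer(inc >= 1),
      specific  = as.integer(inc == k),
      voting    = as.integer(inc >= k / 2 & (k %% 2 == 0 | inc > k / 2))
    )
  }
  structure(out, n_masked = sum(masked))
}

#' Read a decisions CSV into an items-by-raters table
#'
#' Long format has columns `id,rater,decision`; wide format has an `id`
#' column plus one binary column per rater. Either way the result is a wide
#' tibble suitable for [consensus()] and [kappa_matrix()].
#'
#' @param path CSV file path.
#' @param format `"long"` (default) or `"wide"`.
#' @return tibble with `id` plus one 0/1 column per rater.
#' @export
read_decisions <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  df <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (format == "wide") return(tibble::as_tibble(df))
  need <- c("id", "rater", "decision")
  if (!all(need %in% names(df))) {
    stop_data("long decisions CSV needs columns id,rater,decision")
  }
  ids <- unique(df$id)
  out <- tibble::tibble(id = ids)
  for (r in unique(df$rater)) {
    sub <- df[df$rater == r, ]
    out[[r]] <- sub$decision[match(ids, sub$id)]
  }
  out
}

#' Third-expert adjudication of two expert decision vectors
#'
#' Positions where the two experts agree take the shared value; positions
#' where they disagree take the tiebreaking third expert's value. The result
#' is the study's gold standard.
#'
#' @param expert_a,expert_b aligned binary decision vectors.
#' @param tiebreaker binary vector defined (non-NA) at least at every
#'   disagreement position; values elsewhere are ignored.
#' @return list with `gold` (integer vector) and `n_disagreements`.
#' @examples
#' adjudicate(c(1, 0, 1), c(1, 1, 1), tiebreaker = c(NA, 0, NA))
#' @export
adjudicate <- function(expert_a, expert_b, tiebreaker) {
  check_aligned(expert_a, expert_b, "expert_a", "expert_b")
  check_aligned(expert_a, tiebreaker, "expert_a", "tiebreaker")
  check_binary(expert_a, "expert_a")
  check_binary(expert_b, "expert_b")
  check_binary(tiebreaker, "tiebreaker", allow_na = TRUE)

  disagree <- expert_a != expert_b
  if (any(disagree & is.na(tiebreaker))) {
    stop_data("tiebreaker missing at disagreement position ",
              which(disagree & is.na(tiebreaker))[1])
  }
  gold <- as.integer(ifelse(disagree, tiebreaker, expert_a))
  list(gold = gold, n_disagreements = sum(disagree))
}
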