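# Citation corpus ingest: RIS/CSV read-write, deduplication, missing-abstract
# filtering, seeded per-topic sampling.

CORPUS_COLUMNS <- c("id", "title", "abstract", "ref_type", "pub_year",
                    "topic", "source_db")

# Map between RIS tags and corpus columns. Unknown tags on read are ignored;
# the optional doi column round-trips through DO.
RIS_TAGS <- c(ID = "id", TI = "title", AB = "abstract", TY = "ref_type",
              PY = "pub_year", KW = "topic", DB = "source_db", DO = "doi")

new_corpus <- function(df) {
  for (col in CORPUS_COLUMNS) {
    if (!col %in% names(df)) {
      df[[col]] <- rep(if (col == "pub_year") NA_integer_ else "", nrow(df))
    }
  }
  df$pub_year <- suppressWarnings(as.integer(df$pub_year))
  char_cols <- setdiff(intersect(c(CORPUS_COLUMNS, "doi"), names(df)),
                       "pub_year")
  for (col in char_cols) {
    df[[col]] <- ifelse(is.na(df[[col]]), "", as.character(df[[col]]))
  }
  if (anyDuplicated(df$id[df$id != ""])) {
    stop_data("duplicate citation id: ", df$id[duplicated(df$id)][1])
  }
  tibble::as_tibble(df[, c(CORPUS_COLUMNS, intersect("doi", names(df)))])
}

#' Read a citation corpus
#'
#' CSV corpora must carry the documented header
#' `id,title,abstract,ref_type,pub_year,topic,source_db` (an optional `doi`
#' column is honoured by deduplication). RIS corpora use the standard tags
#' TY/TI/AB/PY plus ID, KW (topic), DB (source database) and DO (doi);
#' unrecognised tags are ignored. A record missing its abstract yields an
#' empty string — filtering is a separate, explicit step.
#'
#' @param path file path.
#' @param format `"csv"` or `"ris"`; defaults to the file extension.
#' @return tibble of citations, one row per record.
#' @seealso [write_corpus()], [filter_corpus()]
#' @export
read_corpus <- function(path, format = c("csv", "ris")) {
  if (!file.exists(path)) stop_data("corpus file not found: ", path)
  format <- if (missing(format)) {
    tolower(tools::file_ext(path))
  } else {
    match.arg(format)
  }
  corpus <- switch(format,
    csv = read_corpus_csv(path),
    ris = read_corpus_ris(path),
    stop_param("unsupported corpus format '", format, "'")
  )
  if (nrow(corpus) == 0) warning("empty corpus read from ", path)
  corpus
}

read_corpus_csv <- function(path) {
  df <- read.csv(path, colClasses = "character", check.names = FALSE,
                 fileEncoding = "UTF-8")
  missing_cols <- setdiff(CORPUS_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop_data("CSV corpus missing required columns: ",
              paste(missing_cols, collapse = ", "))
  }
  new_corpus(df)
}

read_corpus_ris <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  records <- list()
  current <- NULL
  tag <- NULL
  record_open <- FALSE
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (grepl("^[A-Z][A-Z0-9]  - ?", line)) {
      this_tag <- substr(line, 1, 2)
      value <- sub("^[A-Z][A-Z0-9]  - ?", "", line)
      if (this_tag == "TY") {
        if (record_open) {
          stop_data("RIS record starting at line ", i,
                    " opened before previous record ended (missing ER)")
        }
        record_open <- TRUE
        current <- list(ref_type = value)
      } else if (this_tag == "ER") {
        if (!record_open) stop_data("stray ER tag at line ", i)
        records[[length(records) + 1]] <- current
        current <- NULL
        record_open <- FALSE
      } else if (record_open && this_tag %in% names(RIS_TAGS)) {
        field <- RIS_TAGS[[this_tag]]
        current[[field]] <- if (is.null(current[[field]])) value else
          paste(current[[field]], value)
      }
      tag <- this_tag
    } else if (record_open && nzchar(trimws(line)) && !is.null(tag) &&
               tag %in% names(RIS_TAGS)) {
      # continuation line: append to the previous tag's value
      field <- RIS_TAGS[[tag]]
      current[[field]] <- paste(current[[field]], trimws(line))
    }
  }
  if (record_open) stop_data("RIS file ends inside a record (missing ER)")
  if (!length(records)) return(new_corpus(data.frame()))
  all_fields <- unique(unlist(lapply(records, names)))
  df <- as.data.frame(
    lapply(setNames(all_fields, all_fields), function(f) {
      vapply(records, function(r) r[[f]] %||% "", character(1))
    }),
    stringsAsFactors = FALSE
  )
  if (!"id" %in% names(df) || any(df$id == "")) {
    auto <- sprintf("ris%05d", seq_len(nrow(df)))
    df$id <- if ("id" %in% names(df)) ifelse(df$id == "", auto, df$id) else auto
  }
  new_corpus(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a citation corpus
#'
#' @param corpus tibble of citations as returned by [read_corpus()].
#' @param path output file path.
#' @param format `"csv"` (RFC-4180, UTF-8) or `"ris"`.
#' @return invisibly, `path`.
#' @export
write_corpus <- function(corpus, path, format = c("csv", "ris")) {
  format <- if (missing(format)) tolower(tools::file_ext(path)) else
    match.arg(format)
  if (format == "csv") {
    write.csv(corpus, path, row.names = FALSE, fileEncoding = "UTF-8",
              na = "")
  } else if (format == "ris") {
    out <- character(0)
    write_order <- c("TY", setdiff(names(RIS_TAGS), c("TY", "ER")))
    for (i in seq_len(nrow(corpus))) {
      for (tg in write_order) {
        field <- if (tg == "TY") "ref_type" else RIS_TAGS[[tg]]
        val <- corpus[[field]][i]
        if (!is.null(val) && !is.na(val) && nzchar(as.character(val))) {
          out <- c(out, sprintf("%s  - %s", tg, val))
        }
      }
      out <- c(out, "ER  - ", "")
    }
    writeLines(out, path, useBytes = TRUE)
  } else {
    stop_param("unsupported corpus format '", format, "'")
  }
  invisible(path)
}

# Normalized-title dedup key: lowercase, strip punctuation, collapse spaces.
normalize_title <- function(title) {
  x <- tolower(title)
  x <- gsub("[^[:alnum:][:space:]]+", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Deduplicate a corpus and drop records without abstracts
#'
#' Duplicates are detected by DOI when both records carry one, otherwise by
#' normalized title (lowercased, punctuation and whitespace collapsed) plus
#' publication year; the first occurrence in input order wins. Records whose
#' abstract is empty after whitespace stripping are then removed. The
#' returned log satisfies
#' `n_final == n_input - n_duplicates_removed - n_missing_abstract_removed`.
#'
#' @param corpus citation tibble.
#' @return list with `corpus` (filtered tibble) and `log` (a
#'   `corpus_filter_log`: `n_input`, `n_duplicates_removed`,
#'   `n_missing_abstract_removed`, `n_final`).
#' @export
filter_corpus <- function(corpus) {
  n_input <- nrow(corpus)
  if (n_input > 0) {
    title_key <- paste0("title:", normalize_title(corpus$title), "|",
                        corpus$pub_year)
    key <- title_key
    if ("doi" %in% names(corpus)) {
      has_doi <- !is.na(corpus$doi) & nzchar(trimws(corpus$doi))
      key[has_doi] <- paste0("doi:", tolower(trimws(corpus$doi[has_doi])))
    }
    dup <- duplicated(key)
    corpus <- corpus[!dup, , drop = FALSE]
    n_dup <- sum(dup)
    missing_abs <- !nzchar(trimws(corpus$abstract))
    corpus <- corpus[!missing_abs, , drop = FALSE]
    n_missing <- sum(missing_abs)
  } else {
    n_dup <- 0L
    n_missing <- 0L
  }
  log <- structure(
    list(n_input = n_input, n_duplicates_removed = n_dup,
         n_missing_abstract_removed = n_missing, n_final = nrow(corpus)),
    class = "corpus_filter_log"
  )
  list(corpus = corpus, log = log)
}

#' @export
print.corpus_filter_log <- function(x, ...) {
  cat(sprintf("Corpus filter: %d in, %d duplicates, %d missing abstracts, %d final\n",
              x$n_input, x$n_duplicates_removed,
              x$n_missing_abstract_removed, x$n_final))
  invisible(x)
}

#' Draw a seeded per-topic random sample
#'
#' Uniform sampling without replacement of up to `per_topic_n` citations per
#' topic; topics smaller than `per_topic_n` are taken whole. One generator is
#' seeded once and topics are processed in sorted topic-name order, so a
#' given (corpus, n, seed) always yields the same sample.
#'
#' @param corpus citation tibble; every record must carry a topic.
#' @param per_topic_n target sample size per topic (default 200).
#' @param seed integer RNG seed.
#' @return list with `sample` (tibble, input order preserved within topic
#'   blocks sorted by topic) and `plan` (list: `per_topic_n`, `seed`,
#'   `proportions` — named fraction sampled per topic).
#' @export
sample_per_topic <- function(corpus, per_topic_n = 200L, seed = 1L) {
  if (any(!nzchar(corpus$topic))) stop_data("every citation needs a topic")
  topics <- sort(unique(corpus$topic))
  withr::with_seed(as.integer(seed), {
    picks <- lapply(topics, function(tp) {
      rows <- which(corpus$topic == tp)
      n_take <- min(per_topic_n, length(rows))
      sort(if (n_take == length(rows)) rows else
        sample(rows, n_take, replace = FALSE))
    })
  })
  sizes <- vapply(topics, function(tp) sum(corpus$topic == tp), integer(1))
  proportions <- setNames(
    vapply(seq_along(topics),
           function(i) min(per_topic_n, sizes[i]) / sizes[i], numeric(1)),
    topics)
  list(
    sample = corpus[unlist(picks), , drop = FALSE],
    plan = list(per_topic_n = as.integer(per_topic_n),
                seed = as.integer(seed), proportions = proportions)
  )
}
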