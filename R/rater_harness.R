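# Prompt assembly, backend contract, reply parsing, screening loop, triage.
#
# A rating backend is any function(prompt_text) -> reply_text. The package
# ships a deterministic keyword-overlap mock for tests and offline runs; a
# live chat-completion backend satisfies the same contract but is deliberately
# not exercised by the test suite.

#' PICOS eligibility frame
#'
#' The Population / Intervention / Comparison / Outcomes / Study-design
#' definition against which each abstract is judged.
#'
#' @param population,intervention,comparison,outcomes,study_design non-empty
#'   component texts.
#' @param topic_title display title of the topic.
#' @return list of class `picos`.
#' @export
picos <- function(population, intervention, comparison, outcomes,
                  study_design, topic_title = "") {
  fields <- list(population = population, intervention = intervention,
                 comparison = comparison, outcomes = outcomes,
                 study_design = study_design)
  empty <- !vapply(fields, function(x) nzchar(trimws(x)), logical(1))
  if (any(empty)) {
    stop_param("PICOS component(s) empty: ",
               paste(names(fields)[empty], collapse = ", "))
  }
  structure(c(fields, list(topic_title = topic_title)), class = "picos")
}

#' Read per-topic PICOS definitions from a YAML config
#'
#' The file maps topic labels to the five PICOS components (plus optional
#' `topic_title`).
#'
#' @param path YAML file path.
#' @return named list of [picos()] objects, one per topic.
#' @export
read_picos <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_param("reading PICOS YAML requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  lapply(raw, function(x) {
    picos(x$population, x$intervention, x$comparison, x$outcomes,
          x$study_design, x$topic_title %||% "")
  })
}

#' Backend configuration for the screening harness
#'
#' @param model_name backend model label (informational for the mock).
#' @param temperature sampling temperature; 0 for deterministic (greedy)
#'   decoding, the setting used for reproducible screening runs.
#' @param max_retries how many times an unparseable reply is re-requested.
#' @param timeout per-request timeout in seconds (live backends).
#' @param seed optional integer seed (mock backend only).
#' @return list of class `backend_config`.
#' @export
backend_config <- function(model_name = "mock", temperature = 0,
                           max_retries = 2L, timeout = 60, seed = NULL) {
  if (temperature < 0) stop_param("temperature must be >= 0")
  if (max_retries < 0) stop_param("max_retries must be >= 0")
  structure(list(model_name = model_name, temperature = temperature,
                 max_retries = as.integer(max_retries), timeout = timeout,
                 seed = seed),
            class = "backend_config")
}

#' Assemble the screening prompt for one citation
#'
#' Renders the versioned prompt template (shipped under
#' `inst/prompts/`) with four blocks in fixed order: a role block, a task
#' block instructing the backend to explain *before* rating and to answer in
#' JSON, an article block (title, abstract, reference type, publication
#' year), and the PICOS block. Deterministic: identical inputs give
#' byte-identical prompts. A citation without an abstract renders an explicit
#' `[no abstract available]` marker.
#'
#' @param citation one-row citation (list or single tibble row) with fields
#'   `title`, `abstract`, `ref_type`, `pub_year`.
#' @param picos a [picos()] object.
#' @param template template name under the package's `prompts/` directory
#'   (without extension).
#' @return single prompt string.
#' @export
build_prompt <- function(citation, picos, template = "default-v1") {
  stopifnot(inherits(picos, "picos"))
  if (!nzchar(trimws(citation$title %||% ""))) {
    stop_data("citation has no title")
  }
  tpl_path <- system.file("prompts", paste0(template, ".txt"),
                          package = "screeneval")
  if (!nzchar(tpl_path)) stop_param("unknown prompt template '", template, "'")
  tpl <- paste(readLines(tpl_path, encoding = "UTF-8", warn = FALSE),
               collapse = "\n")

  abstract <- trimws(citation$abstract %||% "")
  if (!nzchar(abstract)) abstract <- "[no abstract available]"
  year <- citation$pub_year
  fills <- c(
    title = citation$title,
    abstract = abstract,
    ref_type = citation$ref_type %||% "unknown",
    pub_year = if (is.null(year) || is.na(year)) "unknown" else
      as.character(year),
    population = picos$population,
    intervention = picos$intervention,
    comparison = picos$comparison,
    outcomes = picos$outcomes,
    study_design = picos$study_design,
    topic_title = picos$topic_title
  )
  for (key in names(fills)) {
    tpl <- gsub(paste0("{{", key, "}}"), fills[[key]], tpl, fixed = TRUE)
  }
  tpl
}

#' Parse a backend reply into a rating
#'
#' Scans the reply for JSON objects (prose before or after is tolerated),
#' takes the first one containing a `rating` key — the explain-then-rate
#' protocol puts the verdict in the final object, but a single object is the
#' norm — and validates the rating as an integer in 1..5. The `explanation`
#' key is optional; its absence is tolerated (callers may log it).
#'
#' @param text raw reply text.
#' @return list of class `rating`: `value` (integer 1..5), `explanation`
#'   (string, possibly empty).
#' @examples
#' parse_response('{"explanation": "matches population", "rating": 4}')
#' @export
parse_response <- function(text) {
  objs <- extract_json_objects(text)
  if (!length(objs)) {
    stop(errorCondition("no JSON object found in backend reply",
                        class = c("screeneval_parse_error", "error")))
  }
  for (obj in objs) {
    if (!"rating" %in% names(obj)) next
    val <- obj$rating
    if (!is.numeric(val) || length(val) != 1L || is.na(val) ||
        val != as.integer(val) || !(val %in% 1:5)) {
      stop(errorCondition(
        paste0("rating outside the 1-5 scale: ", deparse(val)),
        class = c("screeneval_validation_error", "error")))
    }
    expl <- obj$explanation
    expl <- if (is.null(expl)) "" else as.character(expl)
    return(structure(list(value = as.integer(val), explanation = expl),
                     class = "rating"))
  }
  stop(errorCondition("no JSON object in reply carries a 'rating' key",
                      class = c("screeneval_validation_error", "error")))
}

# Locate balanced {...} spans (string-aware) and parse each with jsonlite,
# keeping those that parse. Returns a list of named lists in text order.
extract_json_objects <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  spans <- list()
  depth <- 0L; start <- NA_integer_
  in_str <- FALSE; escaped <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_str) {
      if (escaped) escaped <- FALSE
      else if (ch == "\\") escaped <- TRUE
      else if (ch == '"') in_str <- FALSE
      next
    }
    if (ch == '"' && depth > 0L) in_str <- TRUE
    else if (ch == "{") {
      if (depth == 0L) start <- i
      depth <- depth + 1L
    } else if (ch == "}" && depth > 0L) {
      depth <- depth - 1L
      if (depth == 0L) {
        spans[[length(spans) + 1]] <- c(start, i)
      }
    }
  }
  out <- list()
  for (sp in spans) {
    candidate <- substr(text, sp[1], sp[2])
    parsed <- tryCatch(jsonlite::fromJSON(candidate, simplifyVector = TRUE),
                       error = function(e) NULL)
    if (is.list(parsed)) out[[length(out) + 1]] <- parsed
  }
  out
}

#' Deterministic keyword-overlap mock backend
#'
#' A rating backend for tests and offline pipelines. It reads the article and
#' PICOS blocks back out of the prompt, tokenizes both, and rates
#' `1 + min(4, floor(overlap / per_point))` where `overlap` is the number of
#' distinct non-trivial PICOS tokens occurring in the article text. Fully
#' deterministic for a fixed prompt.
#'
#' @param per_point how many overlapping keywords buy one rating point
#'   (default 2).
#' @return a backend: `function(prompt) -> reply` where the reply is an
#'   explain-then-rate JSON object.
#' @export
mock_backend <- function(per_point = 2) {
  force(per_point)
  function(prompt) {
    sections <- split_prompt_sections(prompt)
    tok <- function(x) {
      words <- unlist(strsplit(tolower(x), "[^[:alnum:]]+"))
      unique(words[nchar(words) >= 4])
    }
    overlap <- length(intersect(tok(sections$article), tok(sections$picos)))
    rating <- 1 + min(4, overlap %/% per_point)
    jsonlite::toJSON(
      list(explanation = sprintf("%d keyword(s) shared with PICOS", overlap),
           rating = rating),
      auto_unbox = TRUE)
  }
}

# Pull the "## Article" and "## PICOS" blocks from a rendered prompt.
split_prompt_sections <- function(prompt) {
  lines <- strsplit(prompt, "\n", fixed = TRUE)[[1]]
  headers <- grep("^## ", lines)
  bounds <- c(headers, length(lines) + 1L)
  sections <- list(article = "", picos = "")
  for (k in seq_along(headers)) {
    name <- tolower(sub("^## ", "", lines[headers[k]]))
    body <- paste(lines[(headers[k] + 1):(bounds[k + 1] - 1)], collapse = " ")
    if (name %in% names(sections)) sections[[name]] <- body
  }
  sections
}

#' Screen a corpus through a rating backend
#'
#' Builds one prompt per citation, submits it, and parses the reply; a reply
#' that fails to parse or validate is re-requested up to
#' `config$max_retries` times, after which the item's rating is recorded as
#' missing with the failure reason. Partial results are always returned.
#'
#' @param corpus citation tibble (see [read_corpus()]).
#' @param picos_map named list of [picos()] objects keyed by topic; every
#'   topic present in the corpus must be covered.
#' @param backend `function(prompt) -> reply text`.
#' @param config a [backend_config()].
#' @param template prompt template name.
#' @return tibble `id, rating, explanation, n_retries, error` — `rating` is
#'   NA where the backend never produced a valid reply.
#' @export
screen_corpus <- function(corpus, picos_map, backend,
                          config = backend_config(), template = "default-v1") {
  stopifnot(inherits(config, "backend_config"), is.function(backend))
  topics <- unique(corpus$topic)
  uncovered <- setdiff(topics, names(picos_map))
  if (length(uncovered)) {
    stop_param("no PICOS for topic(s): ", paste(uncovered, collapse = ", "))
  }
  n <- nrow(corpus)
  rating <- rep(NA_integer_, n)
  explanation <- character(n)
  n_retries <- integer(n)
  err <- character(n)
  for (i in seq_len(n)) {
    prompt <- build_prompt(corpus[i, ], picos_map[[corpus$topic[i]]],
                           template = template)
    for (attempt in 0:config$max_retries) {
      res <- tryCatch(parse_response(backend(prompt)),
                      error = function(e) e)
      if (inherits(res, "rating")) {
        rating[i] <- res$value
        explanation[i] <- res$explanation
        n_retries[i] <- attempt
        break
      }
      err[i] <- conditionMessage(res)
      n_retries[i] <- attempt
    }
  }
  n_failed <- sum(is.na(rating))
  if (n_failed > 0) {
    warning(sprintf("%d of %d citations have no valid rating after retries",
                    n_failed, n))
  }
  tibble::tibble(id = corpus$id, rating = rating, explanation = explanation,
                 n_retries = n_retries, error = err)
}

#' Two-stage triage of ordinal ratings
#'
#' Splits screening into automatic and human stages: items rated below `low`
#' are auto-excluded, items rated at or above `high` are auto-included, and
#' the indeterminate band in between goes to human review.
#'
#' @param ratings integer ratings in 1..5 (NA allowed → NA label).
#' @param low,high thresholds with `1 <= low <= high <= 5`.
#' @return factor with levels `auto_exclude`, `human_review`, `auto_include`.
#' @examples
#' triage(c(1, 3, 5), low = 2, high = 5)
#' @export
triage <- function(ratings, low = 2L, high = 5L) {
  if (!(low %in% 1:5) || !(high %in% 1:5) || low > high) {
    stop_param("thresholds must satisfy 1 <= low <= high <= 5")
  }
  check_rating_scale(ratings)
  lab <- ifelse(ratings < low, "auto_exclude",
                ifelse(ratings >= high, "auto_include", "human_review"))
  factor(lab, levels = c("auto_exclude", "human_review", "auto_include"))
}
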