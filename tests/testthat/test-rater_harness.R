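test_that("prompts contain all blocks in order and are deterministic", {
  cit <- toy_corpus()[1, ]
  p <- build_prompt(cit, toy_picos())
  blocks <- c("## Role", "## Task", "## Article", "## PICOS")
  pos <- vapply(blocks, function(b) regexpr(b, p, fixed = TRUE)[1], numeric(1))
  expect_true(all(pos > 0))
  expect_true(all(diff(pos) > 0)) # fixed block order
  expect_match(p, cit$title, fixed = TRUE)
  for (lbl in c("Population:", "Intervention:", "Comparison:", "Outcomes:",
                "Study design:")) {
    expect_match(p, lbl, fixed = TRUE)
  }
  # explain-then-rate and JSON instructions live in the task block
  expect_match(p, "explain", ignore.case = TRUE)
  expect_match(p, "JSON", fixed = TRUE)
  expect_identical(p, build_prompt(cit, toy_picos()))

  cit$abstract <- "   "
  expect_match(build_prompt(cit, toy_picos()), "[no abstract available]",
               fixed = TRUE)
  expect_error(build_prompt(cit, toy_picos(), template = "nope"),
               class = "screeneval_param_error")
})

test_that("picos validates its five components", {
  expect_error(picos("adults", "", "sham", "accuracy", "rct"),
               class = "screeneval_param_error")
  expect_s3_class(toy_picos(), "picos")
})

test_that("parse_response extracts and validates ratings", {
  r <- parse_response('{"explanation":"matches population","rating":4}')
  expect_equal(r$value, 4L)
  expect_equal(r$explanation, "matches population")

  # prose preamble before the object
  r2 <- parse_response(
    'Sure! Here is my assessment. {"rating": 5, "explanation": "strong match"}')
  expect_equal(r2$value, 5L)

  # multiple objects: first carrying a rating key wins
  r3 <- parse_response(
    '{"note":"thinking"} and then {"rating":2,"explanation":"weak"} {"rating":5}')
  expect_equal(r3$value, 2L)

  # braces inside strings must not confuse the scanner
  r4 <- parse_response('{"explanation":"shape {a:1} inside","rating":3}')
  expect_equal(r4$value, 3L)

  expect_error(parse_response('{"rating": 7}'),
               class = "screeneval_validation_error")
  expect_error(parse_response("no json here"),
               class = "screeneval_parse_error")
  expect_error(parse_response('{"explanation":"only prose"}'),
               class = "screeneval_validation_error")
})

test_that("serializing a rating and parsing it back is the identity", {
  for (v in 1:5) {
    json <- jsonlite::toJSON(list(explanation = "x", rating = v),
                             auto_unbox = TRUE)
    expect_equal(parse_response(json)$value, v)
  }
})

test_that("the mock backend screens a corpus deterministically", {
  corpus <- do.call(rbind, replicate(4, toy_corpus(), simplify = FALSE))
  corpus$id <- sprintf("c%02d", seq_len(nrow(corpus)))
  pm <- setNames(replicate(6, toy_picos(), simplify = FALSE),
                 unique(corpus$topic))
  res <- screen_corpus(corpus, pm, mock_backend())
  expect_equal(nrow(res), 24)
  expect_equal(sum(is.na(res$rating)), 0)
  expect_true(all(res$rating %in% 1:5))
  res2 <- screen_corpus(corpus, pm, mock_backend())
  expect_identical(res, res2)

  expect_error(screen_corpus(corpus, pm[-1], mock_backend()),
               class = "screeneval_param_error")
})

test_that("unparseable replies are retried and then recorded as missing", {
  # backend that fails twice, then answers
  calls <- 0
  flaky <- function(prompt) {
    calls <<- calls + 1
    if (calls <= 2) "garbage" else '{"rating":4,"explanation":"ok"}'
  }
  res <- screen_corpus(toy_corpus()[1, ],
                       list(COLORECTAL = toy_picos()), flaky,
                       backend_config(max_retries = 2))
  expect_equal(res$rating, 4L)
  expect_equal(res$n_retries, 2L)

  hopeless <- function(prompt) "still garbage"
  expect_warning(
    res2 <- screen_corpus(toy_corpus()[1, ],
                          list(COLORECTAL = toy_picos()), hopeless,
                          backend_config(max_retries = 1)),
    "no valid rating")
  expect_true(is.na(res2$rating))
  expect_match(res2$error, "JSON")
})

test_that("triage partitions every item by the two thresholds", {
  expect_equal(as.character(triage(c(1, 3, 5), low = 2, high = 5)),
               c("auto_exclude", "human_review", "auto_include"))
  expect_true(all(triage(1:5, low = 1, high = 1) == "auto_include"))
  # low = high = 5: no review band, only rating 5 auto-included
  t5 <- triage(1:5, low = 5, high = 5)
  expect_equal(as.character(t5),
               c(rep("auto_exclude", 4), "auto_include"))
  expect_error(triage(1:5, low = 4, high = 2),
               class = "screeneval_param_error")

  set.seed(701)
  r <- sample(1:5, 200, TRUE)
  for (low in 1:4) for (high in low:5) {
    lab <- triage(r, low, high)
    expect_equal(sum(table(lab)), 200) # exactly one label per item
  }
  # raising low never un-excludes an item (monotone exclusion)
  excl2 <- triage(r, 2, 5) == "auto_exclude"
  excl3 <- triage(r, 3, 5) == "auto_exclude"
  expect_true(all(which(excl2) %in% which(excl3)))
})
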