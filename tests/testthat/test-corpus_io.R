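test_that("RIS records parse with standard tags and tolerate missing abstracts", {
  tmp <- withr::local_tempfile(fileext = ".ris")
  writeLines(c(
    "TY  - JOUR", "TI  - First article", "AB  - Abstract one.",
    "PY  - 2020", "KW  - TOPICA", "ER  - ",
    "",
    "TY  - JOUR", "TI  - Second article with a", "  continued title line",
    "PY  - 2021", "KW  - TOPICA", "ER  - ",
    "",
    "TY  - CONF", "TI  - Third", "AB  - Abstract three.", "PY  - 2022",
    "KW  - TOPICB", "ER  - "
  ), tmp)
  corpus <- read_corpus(tmp, "ris")
  expect_equal(nrow(corpus), 3)
  expect_equal(corpus$abstract[2], "") # missing AB is empty, not an error
  expect_equal(corpus$title[2], "Second article with a continued title line")
  expect_equal(corpus$ref_type, c("JOUR", "JOUR", "CONF"))
  expect_equal(corpus$pub_year, 2020:2022)
})

test_that("an empty corpus file reads as an empty corpus with a warning", {
  tmp <- withr::local_tempfile(fileext = ".ris")
  writeLines(character(0), tmp)
  expect_warning(corpus <- read_corpus(tmp, "ris"), "empty")
  expect_equal(nrow(corpus), 0)
})

test_that("malformed RIS and CSV inputs raise informative errors", {
  tmp <- withr::local_tempfile(fileext = ".ris")
  writeLines(c("TY  - JOUR", "TI  - Unterminated record"), tmp)
  expect_error(read_corpus(tmp, "ris"), "ER")

  bad_csv <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = "a", name = "not a corpus"), bad_csv,
            row.names = FALSE)
  expect_error(read_corpus(bad_csv, "csv"), "missing required columns")
  expect_error(read_corpus("no/such/file.csv"), "not found")
})

test_that("CSV and RIS corpora round-trip every field", {
  corpus <- toy_corpus()
  csv <- withr::local_tempfile(fileext = ".csv")
  write_corpus(corpus, csv)
  expect_equal(read_corpus(csv), corpus)

  ris <- withr::local_tempfile(fileext = ".ris")
  write_corpus(corpus, ris)
  back <- read_corpus(ris)
  expect_equal(back, corpus[, names(back)])
})

test_that("filtering removes duplicates then blank abstracts, with exact log", {
  # synthetic corpus matching a published per-topic pipeline: 3263 found,
  # 1564 exact-duplicate injections, 338 of the remainder blank abstracts
  set.seed(611)
  n_unique <- 3263 - 1564
  base <- tibble::tibble(
    id = sprintf("u%04d", 1:n_unique),
    title = sprintf("Unique colorectal imaging study %04d", 1:n_unique),
    abstract = c(rep("", 338), rep("Some abstract.", n_unique - 338)),
    ref_type = "JOUR", pub_year = 2020L, topic = "COLORECTAL",
    source_db = "pubmed"
  )
  dup_rows <- sample(n_unique, 1564, replace = TRUE)
  dups <- base[dup_rows, ]
  dups$id <- sprintf("d%04d", seq_len(nrow(dups)))
  corpus <- rbind(base, dups)[sample(3263), ]
  # keep first occurrences deterministic regardless of shuffle: ids differ
  res <- filter_corpus(corpus)
  expect_equal(res$log$n_input, 3263)
  expect_equal(res$log$n_duplicates_removed, 1564)
  expect_equal(res$log$n_missing_abstract_removed, 338)
  expect_equal(res$log$n_final, 1361)
  expect_equal(res$log$n_final,
               res$log$n_input - res$log$n_duplicates_removed -
                 res$log$n_missing_abstract_removed)
})

test_that("filtering is an identity on a clean corpus and is idempotent", {
  corpus <- toy_corpus()
  res <- filter_corpus(corpus)
  expect_equal(res$corpus, corpus)
  expect_equal(res$log$n_duplicates_removed, 0)
  expect_equal(res$log$n_missing_abstract_removed, 0)

  twice <- filter_corpus(res$corpus)
  expect_equal(twice$corpus, res$corpus)
  expect_equal(twice$log$n_final, twice$log$n_input)
})

test_that("dedup key normalizes case and whitespace, and prefers DOI", {
  pair <- tibble::tibble(
    id = c("a", "b"),
    title = c("CT Colonography: a Review", "ct colonography   a review  "),
    abstract = "Text.", ref_type = "JOUR", pub_year = 2020L,
    topic = "COLORECTAL", source_db = "pubmed"
  )
  res <- filter_corpus(pair)
  expect_equal(res$log$n_duplicates_removed, 1)
  expect_equal(res$corpus$id, "a") # first occurrence wins

  # same normalized title but distinct DOIs: not duplicates
  pair$doi <- c("10.1/x", "10.1/y")
  expect_equal(filter_corpus(pair)$log$n_duplicates_removed, 0)
  # same DOI, different titles: duplicates
  pair$doi <- "10.1/x"
  pair$title <- c("Completely different A", "Completely different B")
  expect_equal(filter_corpus(pair)$log$n_duplicates_removed, 1)
})

test_that("per-topic sampling is seeded, capped, and proportion-logged", {
  n_big <- 1361
  corpus <- tibble::tibble(
    id = sprintf("c%05d", seq_len(n_big + 98)),
    title = "t", abstract = "a", ref_type = "JOUR", pub_year = 2020L,
    topic = c(rep("BIG", n_big), rep("SMALL", 98)), source_db = ""
  )
  s1 <- sample_per_topic(corpus, per_topic_n = 200, seed = 11)
  expect_equal(sum(s1$sample$topic == "BIG"), 200)
  expect_equal(sum(s1$sample$topic == "SMALL"), 98) # undersized topic whole
  expect_equal(round(100 * s1$plan$proportions[["BIG"]], 1), 14.7)
  expect_equal(s1$plan$proportions[["SMALL"]], 1.0)
  expect_true(all(s1$sample$id %in% corpus$id)) # subset of input

  s2 <- sample_per_topic(corpus, per_topic_n = 200, seed = 11)
  expect_identical(s1$sample$id, s2$sample$id) # same seed, same sample
  s3 <- sample_per_topic(corpus, per_topic_n = 200, seed = 12)
  expect_false(identical(s1$sample$id, s3$sample$id))
})

test_that("the packaged per-topic pipeline counts are internally consistent", {
  tab <- study_topic_counts()
  expect_equal(tab$final,
               tab$total_found - tab$duplicates - tab$missing_abstracts)
  # min(200, final) per topic accounts for the full 1198-citation study
  expect_equal(sum(pmin(200L, tab$final)), 1198L)
  expect_equal(round(pmin(200, tab$final) / tab$final, 3),
               tab$sample_proportion, tolerance = 5e-4)
})
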