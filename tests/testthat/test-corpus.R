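test_that("corpus construction enforces its invariants", {
  tl <- tibble::tibble(database = "D", release = c("r1", "r2"),
                       date = c("2001-01-01", "2001-06-01"))
  en <- tibble::tibble(database = "D", release = "r1", entry = "A", text = "x.")
  corp <- versioned_corpus(en, tl)
  expect_s3_class(corp, "versioned_corpus")
  expect_identical(corp$timelines$ordinal, c(1L, 2L))

  # entry referencing an unknown release
  bad <- tibble::tibble(database = "D", release = "r9", entry = "A", text = "x.")
  expect_error(versioned_corpus(bad, tl), "absent from the timeline")
  # duplicate (database, release, entry)
  expect_error(versioned_corpus(dplyr::bind_rows(en, en), tl), "Duplicate")
  # duplicate release ids
  tl_dup <- tibble::tibble(database = "D", release = c("r1", "r1"),
                           date = c("2001-01-01", "2001-06-01"))
  expect_error(versioned_corpus(en, tl_dup), "Duplicate release")
  # decreasing dates
  tl_rev <- tibble::tibble(database = "D", release = c("r1", "r2"),
                           date = c("2002-01-01", "2001-01-01"))
  expect_error(versioned_corpus(en, tl_rev), "non-decreasing")
})

test_that("reading handles empty, singleton and malformed files", {
  f <- withr::local_tempfile()
  writeLines("T\tD\tr1\t2001-01-01", f)
  corp <- read_corpus(f)
  expect_identical(nrow(corp$entries), 0L)
  expect_identical(nrow(corp$timelines), 1L)

  writeLines(c("T\tD\tr1\t2001-01-01", "E\tD\tr1\tA\tx."), f)
  corp <- read_corpus(f)
  expect_identical(corp$entries$text, "x.")

  writeLines(c("T\tD\tr1\t2001-01-01", "garbage line"), f)
  expect_error(read_corpus(f), "line 2")
  writeLines(c("T\tD\tr1\t2001-01-01", "E\tD\tr9\tA\tx."), f)
  expect_error(read_corpus(f), "absent from the timeline")
  expect_error(read_corpus(file.path(tempdir(), "nope.tsv")), "No such file")
})

test_that("write/read round-trips arbitrary corpora and is byte-stable", {
  res <- generate_corpus(synth_config(
    seed = 9, n_databases = 3, n_releases = 3, n_entries = 6,
    vocab_size = 20, n_initial = 3, p_birth = 0.3, p_copy = 0.3,
    p_remove = 0.2))
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  write_corpus(res$corpus, f1)
  back <- read_corpus(f1)
  expect_identical(back$timelines, res$corpus$timelines)
  expect_identical(
    dplyr::arrange(back$entries, database, release, entry),
    dplyr::arrange(res$corpus$entries, database, release, entry))
  write_corpus(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("text escaping survives tabs, newlines and backslashes", {
  tl <- tibble::tibble(database = "D", release = "r1", date = "2001-01-01")
  nasty <- "First line.\nSecond\tpart with \\ backslash. End\\"
  en <- tibble::tibble(database = "D", release = "r1", entry = "A",
                       text = nasty)
  f <- withr::local_tempfile()
  write_corpus(versioned_corpus(en, tl), f)
  expect_length(readLines(f), 2L)  # text stays on one record line
  expect_identical(read_corpus(f)$entries$text, nasty)
})

test_that("the JSON-lines dialect reads interchangeably", {
  f <- withr::local_tempfile()
  writeLines(c(
    '{"database":"D","release":"r1","date":"2001-01-01"}',
    '{"database":"D","release":"r1","entry":"A","text":"Binds DNA."}'), f)
  corp <- read_corpus(f)
  expect_identical(corp$entries$entry, "A")
  expect_identical(corp$timelines$date, as.Date("2001-01-01"))
})

test_that("grouping config files parse in flat and YAML form", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "SwissProt=UniProtKB", "TrEMBL\tUniProtKB"), f)
  g <- read_grouping(f)
  expect_identical(g[["SwissProt"]], "UniProtKB")
  expect_identical(g[["TrEMBL"]], "UniProtKB")
  fy <- withr::local_tempfile(fileext = ".yml")
  writeLines(c("SwissProt: UniProtKB", "InterPro: InterPro"), fy)
  expect_identical(read_grouping(fy)[["SwissProt"]], "UniProtKB")
})

test_that("the DAT adapter reproduces the stored form of a CC block", {
  out <- parse_uniprot_dat(uniprot_cc_fixture(), "SwissProt", "2001_01")
  expect_identical(nrow(out), 1L)
  expect_identical(out$entry, "P47902")
  expect_identical(
    extract_sentences(out$text),
    paste0("may be a transcription factor with important functions in eye ",
           "and nasal development."))
})

test_that("DAT adapter handles missing comments, topics and malformed entries", {
  no_cc <- c("ID   X", "AC   P11111;", "//")
  out <- parse_uniprot_dat(no_cc, "DB", "r1")
  expect_identical(out$text, "")

  two_topics <- c(
    "AC   P22222;",
    "CC   -!- FUNCTION: Binds DNA. Activates transcription",
    "CC   -!- SUBCELLULAR LOCATION: Nucleus.",
    "//")
  out <- parse_uniprot_dat(two_topics, "DB", "r1")
  # sentence count is the sum over topic blocks: topics never fuse even
  # though the first block lacks terminal punctuation
  expect_length(extract_sentences(out$text), 3L)
  out_f <- parse_uniprot_dat(two_topics, "DB", "r1", topics = "FUNCTION")
  expect_length(extract_sentences(out_f$text), 2L)

  no_ac <- c("ID   X", "CC   -!- FUNCTION: Orphan text.", "//")
  expect_warning(out <- parse_uniprot_dat(no_ac, "DB", "r1"), "without AC")
  expect_identical(nrow(out), 0L)

  truncated <- c("AC   P33333;", "CC   -!- FUNCTION: Binds DNA.")
  expect_error(parse_uniprot_dat(truncated, "DB", "r1"), "Truncated")
})

test_that("DAT parsing is order-stable over entry permutations", {
  e1 <- c("AC   P00001;", "CC   -!- FUNCTION: Binds DNA.", "//")
  e2 <- c("AC   P00002;", "CC   -!- FUNCTION: Required for vision.", "//")
  a <- parse_uniprot_dat(c(e1, e2), "DB", "r1")
  b <- parse_uniprot_dat(c(e2, e1), "DB", "r1")
  expect_identical(dplyr::arrange(a, entry), dplyr::arrange(b, entry))
})
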