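two_db_indexes <- function(texts_a, texts_b) {
  mk <- function(db, texts) {
    tl <- tibble::tibble(database = db,
                         release = sprintf("r%d", seq_along(texts)),
                         date = as.Date("2000-01-01") +
                           365 * (seq_along(texts) - 1L))
    en <- tibble::tibble(database = db, release = tl$release,
                         entry = paste0(db, "_E1"), text = texts)
    build_index(versioned_corpus(en, tl))
  }
  list(mk("A", texts_a), mk("B", texts_b))
}

test_that("the shared partition classifies disjoint and shared sentences", {
  ix <- two_db_indexes(
    "One a. Two a. Three a.",
    "One b. Two b. Three b. Four b.")
  part <- shared_partition(ix)
  expect_identical(part$count[part$combination == "A"], 3L)
  expect_identical(part$count[part$combination == "B"], 4L)
  expect_false("A; B" %in% part$combination)
  # conservation: class counts sum to the union of lifetime unique sets
  expect_identical(sum(part$count), 7L)
})

test_that("a sentence in every group lands in the full combination class", {
  sent <- "Visual pigments are the light-absorbing molecules that mediate vision."
  groups <- c("UniProtKB", "InterPro", "neXtProt", "PROSITE", "PRINTS")
  ixs <- lapply(groups, function(g) {
    tl <- tibble::tibble(database = g, release = "r1", date = "2005-01-01")
    en <- tibble::tibble(database = g, release = "r1", entry = paste0(g, "_1"),
                         text = sent)
    build_index(versioned_corpus(en, tl))
  })
  part <- shared_partition(ixs)
  expect_identical(part$combination, paste(sort(groups), collapse = "; "))
  expect_identical(part$count, 1L)
  expect_identical(part$n_groups, 5L)
})

test_that("partition counts match a brute-force membership tally", {
  set.seed(12)
  for (rep in 1:5) {
    res <- generate_corpus(synth_config(
      seed = rep, n_databases = 3, n_releases = 3, n_entries = 5,
      vocab_size = 12, n_initial = 3, p_birth = 0.4, p_remove = 0.3))
    idx <- build_index(res$corpus)
    part <- shared_partition(idx)
    occ <- unique(idx$occurrences[, c("database", "sentence")])
    tally <- tapply(occ$database, occ$sentence, function(d) {
      paste(sort(unique(d)), collapse = "; ")
    })
    want <- table(unlist(tally))
    got <- stats::setNames(part$count, part$combination)
    expect_identical(as.integer(want[names(got)]), unname(got))
    expect_identical(sum(part$count),
                     length(unique(occ$sentence)))
  }
})

test_that("the partition is symmetric under group relabeling", {
  ix <- two_db_indexes("Shared s. Only a.", "Shared s. Only b.")
  p1 <- shared_partition(ix, grouping = c(A = "G1", B = "G2"))
  p2 <- shared_partition(ix, grouping = c(A = "G2", B = "G1"))
  swap <- function(x) {
    vapply(strsplit(chartr("12", "21", x), "; ", fixed = TRUE),
           function(p) paste(sort(p), collapse = "; "), character(1))
  }
  expect_setequal(paste(swap(p1$combination), p1$count),
                  paste(p2$combination, p2$count))
  # a database absent from the map is a config error
  expect_error(shared_partition(ix, grouping = c(A = "G1")), "missing")
  # one group after grouping is not a cross-database question
  expect_error(shared_partition(ix, grouping = c(A = "G", B = "G")),
               "two groups")
})

test_that("date intervals abut and only the last is open", {
  tl <- tibble::tibble(database = "D", release = c("r1", "r2", "r3"),
                       date = as.Date(c("2001-01-01", "2002-01-01",
                                        "2002-07-01")))
  corp <- versioned_corpus(
    tibble::tibble(database = character(), release = character(),
                   entry = character(), text = character()), tl)
  iv <- date_intervals(corp)
  expect_identical(iv$start, tl$date)
  expect_identical(iv$end[1:2], tl$date[2:3])
  expect_true(is.na(iv$end[3]))
  # single release: one open interval
  iv1 <- date_intervals(corp, database = "D")[1, ]
  expect_identical(iv1$start, as.Date("2001-01-01"))
  # property: intervals of one database never overlap
  set.seed(2)
  for (rep in 1:10) {
    n <- sample(2:6, 1)
    dates <- sort(as.Date("2000-01-01") + sample(0:2000, n))
    tl2 <- tibble::tibble(database = "X", release = sprintf("r%d", 1:n),
                          date = dates)
    iv2 <- date_intervals(
      dplyr::mutate(tl2, ordinal = dplyr::row_number()))
    closed <- iv2[!is.na(iv2$end), ]
    expect_true(all(closed$end >= closed$start))
    if (nrow(closed) > 1) {
      expect_true(all(closed$end[-nrow(closed)] <= closed$start[-1] |
                        closed$end[-nrow(closed)] == closed$start[-1]))
    }
  }
})

test_that("the cross-database search recovers the two-database reconstruction", {
  fx <- fig3_corpora()
  src_idx <- build_index(fx$source)
  tgt_idx <- build_index(fx$target)
  # invisible within each database alone
  expect_identical(nrow(detect_missing_origin(src_idx, "PRINTS")), 0L)
  expect_identical(nrow(detect_missing_origin(tgt_idx, "InterPro")), 0L)
  # but exactly one ordered candidate across the pair
  cand <- cross_missing_origin(list(src_idx, tgt_idx), "PRINTS", "InterPro")
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$direction_confidence, "ordered")
  expect_true(cand$target_still_present)
  expect_true(cand$source_first_start < cand$target_first_start)
})

test_that("nothing removed from the source means no candidate", {
  ix <- two_db_indexes(
    c("Kept sentence always.", "Kept sentence always."),
    c("Kept sentence always.", "Kept sentence always."))
  cand <- cross_missing_origin(ix, "A", "B")
  expect_identical(nrow(cand), 0L)
  expect_error(cross_missing_origin(ix, "A", "A"), "must differ")
  expect_error(cross_missing_origin(ix, "A", "Z"), "Unknown group")
})

test_that("candidates never claim a reversed timeline", {
  set.seed(77)
  for (rep in 1:5) {
    res <- generate_corpus(synth_config(
      seed = rep + 500, n_databases = 2, n_releases = 6, n_entries = 8,
      vocab_size = 15, n_initial = 3, p_birth = 0.4, p_copy = 0.4,
      p_remove = 0.4,
      planted = c(cross_missing_origin = 2)))
    idx <- build_index(res$corpus)
    cand <- cross_missing_origin(idx, "D1", "D2")
    if (nrow(cand)) {
      tf_end <- cand$target_first_end
      tf_end[is.na(tf_end)] <- as.Date("9999-12-31")
      expect_true(all(tf_end > cand$source_first_start))
      expect_true(all(cand$source_first_start <= cand$target_first_start))
    }
  }
})

test_that("planted cross-database instances are recovered exactly", {
  res <- generate_corpus(synth_config(
    seed = 42, n_databases = 2, n_releases = 12, n_entries = 40,
    vocab_size = 40, n_initial = 4,
    planted = c(cross_missing_origin = 10)))
  idx <- build_index(res$corpus)
  cand <- cross_missing_origin(idx, "D1", "D2")
  cand2 <- cross_missing_origin(idx, "D2", "D1")
  planted <- res$truth$sentence[res$truth$label == "cross_missing_origin"]
  recovered <- c(cand$sentence, cand2$sentence)
  expect_setequal(recovered, planted)
  expect_true(all(c(cand$direction_confidence,
                    cand2$direction_confidence) == "ordered"))
})

test_that("overlapping calendars flag candidates as ambiguous", {
  res <- generate_corpus(synth_config(
    seed = 3, n_databases = 2, n_releases = 8, n_entries = 10,
    vocab_size = 15, n_initial = 3, cross_overlap = TRUE,
    planted = c(cross_missing_origin = 3)))
  idx <- build_index(res$corpus)
  cand <- dplyr::bind_rows(cross_missing_origin(idx, "D1", "D2"),
                           cross_missing_origin(idx, "D2", "D1"))
  planted <- res$truth$sentence[res$truth$label == "cross_missing_origin"]
  hit <- cand[cand$sentence %in% planted, ]
  expect_identical(nrow(hit), 3L)
  expect_true(all(hit$direction_confidence == "ambiguous"))
})

test_that("the crossdb report writes partition TSV and candidate JSONL", {
  fx <- fig3_corpora()
  ixs <- list(build_index(fx$source), build_index(fx$target))
  part <- shared_partition(ixs)
  cand <- cross_missing_origin(ixs, "PRINTS", "InterPro")
  fp <- withr::local_tempfile(fileext = ".tsv")
  fc <- withr::local_tempfile(fileext = ".jsonl")
  write_crossdb_report(part, fp, candidates = cand, candidates_path = fc)
  back <- readr::read_tsv(fp, show_col_types = FALSE)
  expect_identical(back$combination[1], "InterPro; PRINTS")
  rec <- jsonlite::fromJSON(readLines(fc)[1])
  expect_identical(rec$direction_confidence, "ordered")
})
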