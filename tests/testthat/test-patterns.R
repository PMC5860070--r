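test_that("transient detection follows the single-release-run definition", {
  # timeline r1 < r2 < r3; sentence in entry A at r1 only -> transient
  idx <- build_index(corpus_one_sentence(
    rbind(A = c(TRUE, FALSE, FALSE))))
  tr <- detect_transient(idx, "D")
  expect_identical(tr$sentence, "probe sentence one.")
  expect_identical(tr$start_idx, 1L)

  # present at every release -> not transient
  idx2 <- build_index(corpus_one_sentence(rbind(A = c(TRUE, TRUE, TRUE))))
  expect_identical(nrow(detect_transient(idx2, "D")), 0L)

  # run touching the latest release is censored, not transient
  idx3 <- build_index(corpus_one_sentence(rbind(A = c(FALSE, FALSE, TRUE))))
  expect_identical(nrow(detect_transient(idx3, "D")), 0L)
  expect_identical(detect_possibly_transient(idx3, "D")$sentence,
                   "probe sentence one.")

  # single-release database: transience unobservable
  idx4 <- build_index(corpus_one_sentence(rbind(A = TRUE)))
  expect_error(detect_transient(idx4, "D"), "single release")
})

test_that("possibly-transient means new in the latest release, with precedence", {
  # present at r2 and r3 (latest): run length 2, not possibly transient
  idx <- build_index(corpus_one_sentence(rbind(A = c(FALSE, TRUE, TRUE))))
  expect_identical(nrow(detect_possibly_transient(idx, "D")), 0L)

  # removed length-1 run in A plus new length-1 run at latest in B:
  # transient wins, the sentence is not double-counted
  idx2 <- build_index(corpus_one_sentence(
    rbind(A = c(TRUE, FALSE, FALSE), B = c(FALSE, FALSE, TRUE))))
  expect_identical(nrow(detect_transient(idx2, "D")), 1L)
  expect_identical(nrow(detect_possibly_transient(idx2, "D")), 0L)

  # single-release database is legal here: everything is new
  idx3 <- build_index(corpus_one_sentence(rbind(A = TRUE)))
  expect_identical(nrow(detect_possibly_transient(idx3, "D")), 1L)
})

test_that("the missing-origin detector reproduces the published timeline", {
  idx <- build_index(fig2_corpus())
  mo <- detect_missing_origin(idx, "InterPro")
  expect_identical(nrow(mo), 1L)
  expect_identical(mo$origin_entries[[1]], "IPR004086")
  expect_identical(mo$surviving_entries[[1]], "IPR005430")
  expect_identical(mo$first_idx, 1L)   # debut in 2001
  expect_identical(mo$removal_idx, 3L) # origin loses the sentence in 2003
  # and the sentence is not transient in either entry (both runs length 2)
  expect_identical(nrow(detect_transient(idx, "InterPro")), 0L)
})

test_that("removal without a surviving secondary is not missing origin", {
  idx <- build_index(corpus_one_sentence(
    rbind(A = c(TRUE, TRUE, FALSE, FALSE))))
  expect_identical(nrow(detect_missing_origin(idx, "D")), 0L)
  # fewer than 3 releases is rejected
  idx2 <- build_index(corpus_one_sentence(rbind(A = c(TRUE, FALSE))))
  expect_error(detect_missing_origin(idx2, "D"), "fewer than 3")
})

test_that("simultaneous debuts share origin status and secondaries must debut later", {
  # both entries debut at r1: no secondary exists, whatever happens later
  idx <- build_index(corpus_one_sentence(
    rbind(A = c(TRUE, TRUE, FALSE), B = c(TRUE, TRUE, TRUE))))
  expect_identical(nrow(detect_missing_origin(idx, "D")), 0L)
  # degenerate propagation: secondary debuts exactly at the removal release
  idx2 <- build_index(corpus_one_sentence(
    rbind(A = c(TRUE, TRUE, FALSE), B = c(FALSE, FALSE, TRUE))))
  mo <- detect_missing_origin(idx2, "D")
  expect_identical(nrow(mo), 1L)
  expect_identical(mo$removal_idx, 3L)
})

test_that("detectors agree with the brute-force oracle on exhaustive 2x3 matrices", {
  fx <- index_from_all_matrices(n_entries = 2L, n_releases = 3L)
  tr <- detect_transient(fx$index, "D")$sentence
  pt <- detect_possibly_transient(fx$index, "D")$sentence
  mo <- detect_missing_origin(fx$index, "D")$sentence
  for (k in fx$codes) {
    pres <- presence_from_code(k, 2L, 3L)
    want <- oracle_labels(pres)
    s <- fx$sentences[k]
    expect_identical(s %in% tr, unname(want["transient"]), label = s)
    expect_identical(s %in% pt, unname(want["possibly_transient"]), label = s)
    expect_identical(s %in% mo, unname(want["missing_origin"]), label = s)
  }
})

test_that("pattern summary counts planted instances exactly", {
  res <- generate_corpus(synth_config(
    seed = 42, n_releases = 6, n_entries = 30, vocab_size = 40,
    n_initial = 4, planted = c(transient = 5, missing_origin = 3)))
  idx <- build_index(res$corpus)
  summ <- pattern_summary(idx, "D1")
  expect_identical(summ$missing_origin, 3L)
  expect_identical(summ$transient, 5L)
  expect_identical(summ$possibly_transient, 0L)
  # recovered sentence sets equal the planted ones
  expect_setequal(detect_transient(idx, "D1")$sentence,
                  res$truth$sentence[res$truth$label == "transient"])
  expect_setequal(detect_missing_origin(idx, "D1")$sentence,
                  res$truth$sentence[res$truth$label == "missing_origin"])
})

test_that("labels are disjoint under the precedence rule", {
  set.seed(4)
  for (rep in 1:5) {
    res <- generate_corpus(synth_config(
      seed = rep * 100, n_releases = 5, n_entries = 8, vocab_size = 15,
      n_initial = 3, p_birth = 0.4, p_copy = 0.4, p_remove = 0.4))
    idx <- build_index(res$corpus)
    tr <- detect_transient(idx, "D1")$sentence
    pt <- detect_possibly_transient(idx, "D1")$sentence
    expect_length(intersect(tr, pt), 0L)
  }
})

test_that("pattern evidence re-validates against the index", {
  idx <- build_index(fig2_corpus())
  mo <- detect_missing_origin(idx, "InterPro")
  # claimed origin run exists and is maximal: check via presence_runs
  runs <- presence_runs(idx, mo$sentence, "InterPro", mo$origin_entries[[1]])
  expect_identical(runs$start_idx, mo$first_idx)
  expect_identical(runs$end_idx, mo$removal_idx - 1L)
  # survivors hold the sentence at the removal release
  surv <- occurrences_of(idx, mo$sentence, "InterPro")
  expect_true(any(surv$entry == mo$surviving_entries[[1]] &
                    surv$ordinal == mo$removal_idx))
})

test_that("pattern reports export summary TSV and evidence JSONL", {
  res <- generate_corpus(synth_config(
    seed = 42, n_releases = 6, n_entries = 20, vocab_size = 30,
    n_initial = 3, planted = c(transient = 2, missing_origin = 1)))
  idx <- build_index(res$corpus)
  fs <- withr::local_tempfile(fileext = ".tsv")
  fe <- withr::local_tempfile(fileext = ".jsonl")
  write_pattern_report(idx, fs, evidence_path = fe)
  summ <- readr::read_tsv(fs, show_col_types = FALSE)
  expect_identical(names(summ),
                   c("database", "missing_origin", "transient",
                     "possibly_transient"))
  ev <- lapply(readLines(fe), jsonlite::fromJSON)
  expect_length(ev, 3L)
  expect_setequal(vapply(ev, `[[`, "", "label"),
                  c("missing_origin", "transient", "transient"))
})
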