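#' Configuration for the synthetic versioned-corpus generator
#'
#' Describes a multi-database, multi-release annotation ecosystem: per
#' database a release calendar (number of releases, start date, period in
#' days), a fixed entry population, a sentence vocabulary, per-release
#' background process rates (sentence birth, intra-database copy with a
#' one-release lag, removal, edit) and the number of pattern instances to
#' plant with ground truth. By default sibling databases start half a period
#' apart so cross-database release intervals order strictly; `cross_overlap`
#' aligns the calendars instead, which makes planted cross-database
#' candidates ambiguous in direction — useful for testing the confidence
#' flag. `cross_edit` forces an edit on the target copy of every planted
#' cross-database instance, simulating the small textual corrections that
#' break an exact-match provenance trail.
#'
#' Planted sentences carry a reserved token (`xxplanted`) never used by the
#' background vocabulary, so background collisions are impossible and
#' recovery metrics are exact.
#'
#' @param seed Integer random seed; generation is a pure function of the
#'   config including the seed.
#' @param databases Data frame with columns `label`, `n_releases`,
#'   `start_date`, `period_days`; `NULL` builds `n_databases` regular
#'   calendars `D1`, `D2`, ... with the offsets described above.
#' @param n_databases,n_releases,start_date,period_days Used only when
#'   `databases` is `NULL`.
#' @param n_entries Entries per database (present at every release).
#' @param vocab_size Number of distinct background sentence templates.
#' @param n_initial Background sentences drawn (with replacement) per entry
#'   at the first release.
#' @param p_birth,p_copy,p_remove,p_edit Per-entry, per-release probabilities
#'   of the background processes, each in `[0, 1]`.
#' @param planted Named counts of pattern instances to plant:
#'   `transient`, `possibly_transient`, `missing_origin`,
#'   `cross_missing_origin` (missing names default to 0).
#' @param cross_overlap Align all calendars (see above).
#' @param cross_edit Edit target copies of cross-database plants (see above).
#' @param grouping Optional database -> group mapping for the corpus.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed = 1L, databases = NULL, n_databases = 1L,
                         n_releases = 6L, start_date = "2000-01-01",
                         period_days = 365L, n_entries = 20L,
                         vocab_size = 100L, n_initial = 5L,
                         p_birth = 0, p_copy = 0, p_remove = 0, p_edit = 0,
                         planted = c(transient = 0L), cross_overlap = FALSE,
                         cross_edit = FALSE, grouping = NULL) {
  if (is.null(databases)) {
    offs <- if (cross_overlap) rep(0L, n_databases) else
      round((seq_len(n_databases) - 1L) * period_days / 2)
    databases <- tibble(
      label = paste0("D", seq_len(n_databases)),
      n_releases = as.integer(n_releases),
      start_date = as.Date(start_date) + offs,
      period_days = as.integer(period_days))
  } else {
    databases <- as_tibble(databases)
    databases$start_date <- as.Date(databases$start_date)
  }
  full <- c(transient = 0L, possibly_transient = 0L, missing_origin = 0L,
            cross_missing_origin = 0L)
  planted <- unlist(planted)
  bad <- setdiff(names(planted), names(full))
  if (length(bad)) abort(paste0("Unknown planted label(s): ",
                                paste(bad, collapse = ", ")))
  full[names(planted)] <- as.integer(planted)
  rates <- c(p_birth = p_birth, p_copy = p_copy, p_remove = p_remove,
             p_edit = p_edit)
  if (any(rates < 0 | rates > 1)) abort("Background rates must be in [0, 1].")
  if (any(full < 0L)) abort("Planted counts must be >= 0.")
  if (full[["transient"]] > 0L && all(databases$n_releases < 2L)) {
    abort("Planting transient instances needs a database with >= 2 releases.")
  }
  if (full[["missing_origin"]] > 0L && all(databases$n_releases < 3L)) {
    abort("Planting missing-origin instances needs >= 3 releases.")
  }
  if (full[["cross_missing_origin"]] > 0L && nrow(databases) < 2L) {
    abort("Planting cross-database instances needs >= 2 databases.")
  }
  structure(list(seed = as.integer(seed), databases = databases,
                 n_entries = as.integer(n_entries),
                 vocab_size = as.integer(vocab_size),
                 n_initial = as.integer(n_initial),
                 p_birth = p_birth, p_copy = p_copy, p_remove = p_remove,
                 p_edit = p_edit, planted = full,
                 cross_overlap = isTRUE(cross_overlap),
                 cross_edit = isTRUE(cross_edit), grouping = grouping),
            class = "synth_config")
}

#' Read a generator config from a YAML file
#'
#' Keys mirror the arguments of [synth_config()]; `databases` may be a list
#' of mappings with `label`, `n_releases`, `start_date`, `period_days`.
#'
#' @param path Path to a YAML config.
#' @return A `synth_config`.
#' @export
read_synth_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$databases)) {
    y$databases <- bind_rows(lapply(y$databases, as_tibble))
  }
  if (!is.null(y$grouping)) y$grouping <- unlist(y$grouping)
  do.call(synth_config, y)
}

#' Apply a provenance-breaking edit to a sentence
#'
#' Substitutes one token of the sentence with a word from a fixed synonym
#' table (trailing punctuation preserved), guaranteeing the result differs
#' from the input. Used by the background edit process to simulate the small
#' grammatical or textual corrections that break an exact-match provenance
#' trail. Deterministic under a fixed RNG state.
#'
#' @param sentence A normalized sentence with at least 2 tokens.
#' @return The edited sentence.
#' @export
edit_sentence <- function(sentence) {
  toks <- strsplit(sentence, " ", fixed = TRUE)[[1]]
  if (length(toks) < 2L) {
    abort("edit_sentence() needs a sentence with at least 2 tokens.")
  }
  synonyms <- c("protein", "enzyme", "receptor", "domain", "kinase",
                "factor", "complex", "subunit", "homolog", "regulator")
  i <- sample.int(length(toks), 1L)
  tok <- toks[i]
  core <- gsub("[^a-z0-9]+$", "", tok)
  trail <- substr(tok, nchar(core) + 1L, nchar(tok))
  repl <- sample(synonyms, 1L)
  if (repl == core) repl <- synonyms[(match(repl, synonyms) %% length(synonyms)) + 1L]
  toks[i] <- paste0(repl, trail)
  paste(toks, collapse = " ")
}

# draw a planting site; feasibility was checked by synth_config / generate
plant_schedule <- function(config, calendars) {
  dbs <- config$databases
  ent_ids <- function(db) sprintf("%s_E%03d", db, seq_len(config$n_entries))
  plant <- list()   # rows: database, entry, ordinal, sentence
  truth <- list()
  add <- function(db, entry, ords, sentence) {
    plant[[length(plant) + 1L]] <<- tibble(database = db, entry = entry,
                                           ordinal = as.integer(ords),
                                           sentence = sentence)
  }
  mk <- function(label, i) {
    paste0("xxplanted ", gsub("_", " ", label), " instance ",
           sprintf("%04d", i), " marker sentence.")
  }
  p <- config$planted

  ok2 <- dbs$label[dbs$n_releases >= 2L]
  for (i in seq_len(p[["transient"]])) {
    db <- if (length(ok2) == 1L) ok2 else sample(ok2, 1L)
    R <- dbs$n_releases[dbs$label == db]
    entry <- sample(ent_ids(db), 1L)
    r <- sample.int(R - 1L, 1L)
    s <- mk("transient", i)
    add(db, entry, r, s)
    truth[[length(truth) + 1L]] <- tibble(
      label = "transient", sentence = s, sentence2 = s, database = db,
      entry = entry, start_idx = r, end_idx = r,
      database2 = NA_character_, entry2 = NA_character_,
      start2_idx = NA_integer_, end2_idx = NA_integer_,
      removal_idx = NA_integer_)
  }

  for (i in seq_len(p[["possibly_transient"]])) {
    db <- if (nrow(dbs) == 1L) dbs$label else sample(dbs$label, 1L)
    R <- dbs$n_releases[dbs$label == db]
    entry <- sample(ent_ids(db), 1L)
    s <- mk("possibly_transient", i)
    add(db, entry, R, s)
    truth[[length(truth) + 1L]] <- tibble(
      label = "possibly_transient", sentence = s, sentence2 = s,
      database = db, entry = entry, start_idx = R, end_idx = R,
      database2 = NA_character_, entry2 = NA_character_,
      start2_idx = NA_integer_, end2_idx = NA_integer_,
      removal_idx = NA_integer_)
  }

  ok3 <- dbs$label[dbs$n_releases >= 3L]
  for (i in seq_len(p[["missing_origin"]])) {
    db <- if (length(ok3) == 1L) ok3 else sample(ok3, 1L)
    R <- dbs$n_releases[dbs$label == db]
    ab <- sample(ent_ids(db), 2L)
    f <- sample.int(R - 2L, 1L)
    m <- f + 2L
    e2 <- min(f + 3L, R)
    s <- mk("missing_origin", i)
    add(db, ab[1], f:(f + 1L), s)         # origin: debut, survive one, drop at m
    add(db, ab[2], (f + 1L):e2, s)        # secondary: debuts after f, holds at m
    truth[[length(truth) + 1L]] <- tibble(
      label = "missing_origin", sentence = s, sentence2 = s, database = db,
      entry = ab[1], start_idx = f, end_idx = f + 1L,
      database2 = db, entry2 = ab[2], start2_idx = f + 1L, end2_idx = e2,
      removal_idx = m)
  }

  if (p[["cross_missing_origin"]] > 0L) {
    for (i in seq_len(p[["cross_missing_origin"]])) {
      pair <- sample(dbs$label, 2L)
      sdb <- pair[1]; tdb <- pair[2]
      Rs <- dbs$n_releases[dbs$label == sdb]
      Rt <- dbs$n_releases[dbs$label == tdb]
      sdates <- calendars[[sdb]]; tdates <- calendars[[tdb]]
      feas <- integer(0)
      for (a in seq_len(max(Rs - 2L, 0L))) {
        b <- a + 1L
        c0 <- if (config$cross_overlap) {
          # align first-seen intervals: debut target with the source debut
          if (tdates[a] == sdates[a] && a >= b - 1L) a else NA_integer_
        } else {
          w <- which(tdates >= sdates[b])
          if (length(w)) min(w) else NA_integer_
        }
        if (!is.na(c0) && c0 <= Rt - 1L &&
            (config$cross_overlap || tdates[c0] >= sdates[b])) {
          feas <- c(feas, a)
        }
      }
      if (!length(feas)) {
        abort("Infeasible cross-database planting for the given calendars.")
      }
      a <- if (length(feas) == 1L) feas else sample(feas, 1L)
      b <- a + 1L
      c0 <- if (config$cross_overlap) a else min(which(tdates >= sdates[b]))
      sentry <- sample(ent_ids(sdb), 1L)
      tentry <- sample(ent_ids(tdb), 1L)
      s <- mk("cross_missing_origin", i)
      s2 <- if (config$cross_edit) edit_sentence(s) else s
      add(sdb, sentry, a:b, s)
      add(tdb, tentry, c0:Rt, s2)
      truth[[length(truth) + 1L]] <- tibble(
        label = "cross_missing_origin", sentence = s, sentence2 = s2,
        database = sdb, entry = sentry, start_idx = a, end_idx = b,
        database2 = tdb, entry2 = tentry, start2_idx = c0, end2_idx = Rt,
        removal_idx = b + 1L)
    }
  }

  list(plant = if (length(plant)) bind_rows(plant) else
         tibble(database = character(), entry = character(),
                ordinal = integer(), sentence = character()),
       truth = if (length(truth)) bind_rows(truth) else
         tibble(label = character(), sentence = character(),
                sentence2 = character(), database = character(),
                entry = character(), start_idx = integer(),
                end_idx = integer(), database2 = character(),
                entry2 = character(), start2_idx = integer(),
                end2_idx = integer(), removal_idx = integer()))
}

#' Generate a synthetic versioned corpus with planted ground truth
#'
#' Simulates the configured ecosystem release by release: every entry starts
#' with `n_initial` background sentences at the first release, then per
#' release may gain a newly born sentence, copy a sentence that another entry
#' carried at the previous release (one-release propagation lag, the smallest
#' observable), lose a sentence, or have a sentence edited. Planted pattern
#' instances are written on top of the background at exactly the releases
#' their definitions require, so every planted instance satisfies the
#' corresponding detector's conditions by construction, and background never
#' touches planted sentences. With all rates zero and nothing planted, every
#' sentence born at the first release persists to the last.
#'
#' Generation is deterministic: identical config (including seed) gives a
#' byte-identical corpus.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_result` with elements `corpus` (a
#'   [versioned_corpus()]) and `truth` (the planted ground-truth tibble; see
#'   [verify_ground_truth()]).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, generate_corpus_impl(config))
}

generate_corpus_impl <- function(config) {
  dbs <- config$databases
  calendars <- list()
  tl <- list()
  for (i in seq_len(nrow(dbs))) {
    dates <- dbs$start_date[i] + (seq_len(dbs$n_releases[i]) - 1L) *
      dbs$period_days[i]
    calendars[[dbs$label[i]]] <- dates
    tl[[i]] <- tibble(database = dbs$label[i],
                      release = sprintf("r%02d", seq_len(dbs$n_releases[i])),
                      date = dates)
  }
  timelines <- bind_rows(tl)

  vocab_tokens <- sprintf("t%03d", seq_len(max(4L * config$vocab_size, 50L)))
  vocab <- vapply(seq_len(config$vocab_size), function(v) {
    n <- sample(4:8, 1L)
    paste0(paste(c(sample(vocab_tokens, n, replace = TRUE),
                   sprintf("v%04d", v)), collapse = " "), ".")
  }, character(1))

  sched <- plant_schedule(config, calendars)
  plant_key <- paste(sched$plant$database, sched$plant$entry,
                     sched$plant$ordinal, sep = "\r")

  entries <- list()
  for (db in dbs$label) {
    R <- dbs$n_releases[dbs$label == db]
    ids <- sprintf("%s_E%03d", db, seq_len(config$n_entries))
    state <- stats::setNames(
      lapply(ids, function(e) sample(vocab, config$n_initial, replace = TRUE)),
      ids)
    prev <- state
    for (r in seq_len(R)) {
      if (r > 1L) {
        prev_snapshot <- state
        for (e in ids) {
          if (stats::runif(1) < config$p_birth) {
            state[[e]] <- c(state[[e]], sample(vocab, 1L))
          }
          if (stats::runif(1) < config$p_copy && config$n_entries > 1L) {
            donor <- sample(setdiff(ids, e), 1L)
            pool <- prev[[donor]]
            if (length(pool)) state[[e]] <- c(state[[e]], sample(pool, 1L))
          }
          if (stats::runif(1) < config$p_remove && length(state[[e]])) {
            state[[e]] <- state[[e]][-sample.int(length(state[[e]]), 1L)]
          }
          if (stats::runif(1) < config$p_edit && length(state[[e]])) {
            j <- sample.int(length(state[[e]]), 1L)
            state[[e]][j] <- edit_sentence(state[[e]][j])
          }
        }
        prev <- prev_snapshot
      }
      for (e in ids) {
        here <- plant_key == paste(db, e, r, sep = "\r")
        text <- paste(c(state[[e]], sched$plant$sentence[here]),
                      collapse = " ")
        entries[[length(entries) + 1L]] <- tibble(
          database = db, release = sprintf("r%02d", r), entry = e,
          text = text)
      }
    }
  }
  corpus <- versioned_corpus(bind_rows(entries), timelines,
                             grouping = config$grouping)
  structure(list(corpus = corpus, truth = sched$truth, config = config),
            class = "synth_result")
}

#' @export
print.synth_result <- function(x, ...) {
  cat("<synth_result>\n")
  print(x$corpus)
  cat("  planted instances: ", nrow(x$truth), "\n", sep = "")
  invisible(x)
}

#' Verify planted ground truth against a generated corpus
#'
#' Re-checks every planted tuple directly against the corpus text: the
#' sentence must be present in the recorded entries at the recorded releases
#' and absent at the releases flanking them that the pattern definition
#' requires (removal after a transient run, origin loss at the removal
#' release, absence from the source's latest release for cross-database
#' plants). A valid generator output yields zero violations; violations are
#' data, not errors.
#'
#' @param corpus A [versioned_corpus()] (or a `synth_result`).
#' @param truth Ground-truth tibble as produced by [generate_corpus()];
#'   defaults to the one inside a `synth_result`.
#' @return Tibble of violations with columns `label`, `sentence`, `problem`;
#'   zero rows when everything checks out.
#' @export
verify_ground_truth <- function(corpus, truth = NULL) {
  if (inherits(corpus, "synth_result")) {
    if (is.null(truth)) truth <- corpus$truth
    corpus <- corpus$corpus
  }
  stopifnot(inherits(corpus, "versioned_corpus"))
  idx <- build_index(corpus)
  occ <- idx$occurrences
  have <- unique(paste(occ$database, occ$entry, occ$ordinal, occ$sentence,
                       sep = "\r"))
  present <- function(db, entry, ords, s) {
    paste(db, entry, ords, s, sep = "\r") %in% have
  }
  nrel <- tapply(idx$timelines$ordinal, idx$timelines$database, max)

  bad <- list()
  flag <- function(label, s, problem) {
    bad[[length(bad) + 1L]] <<- tibble(label = label, sentence = s,
                                       problem = problem)
  }
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    key <- normalize_sentence(tr$sentence)
    key2 <- normalize_sentence(tr$sentence2)
    R <- nrel[[tr$database]]
    span <- tr$start_idx:tr$end_idx
    if (!all(present(tr$database, tr$entry, span, key))) {
      flag(tr$label, key, "sentence missing from its planted presence span")
      next
    }
    if (tr$start_idx > 1L &&
        present(tr$database, tr$entry, tr$start_idx - 1L, key)) {
      flag(tr$label, key, "sentence present before its planted debut")
    }
    if (tr$label %in% c("transient", "missing_origin", "cross_missing_origin")) {
      if (tr$end_idx + 1L <= R &&
          present(tr$database, tr$entry, tr$end_idx + 1L, key)) {
        flag(tr$label, key, "sentence not removed after its planted span")
      }
      if (tr$label == "transient" && tr$end_idx >= R) {
        flag(tr$label, key, "transient plant touches the latest release")
      }
    }
    if (tr$label == "possibly_transient" && tr$start_idx != R) {
      flag(tr$label, key, "possibly-transient plant not in the latest release")
    }
    if (!is.na(tr$entry2)) {
      span2 <- tr$start2_idx:tr$end2_idx
      if (!all(present(tr$database2, tr$entry2, span2, key2))) {
        flag(tr$label, key, "secondary/target entry missing the sentence")
      }
      if (tr$start2_idx > 1L &&
          present(tr$database2, tr$entry2, tr$start2_idx - 1L, key2)) {
        flag(tr$label, key, "secondary/target debut earlier than planted")
      }
      if (tr$label == "missing_origin" &&
          !present(tr$database2, tr$entry2, tr$removal_idx, key2)) {
        flag(tr$label, key, "no survivor at the removal release")
      }
      if (tr$label == "cross_missing_origin" &&
          tr$end2_idx != nrel[[tr$database2]]) {
        flag(tr$label, key, "target plant does not reach the latest release")
      }
    }
  }
  if (!length(bad)) {
    return(tibble(label = character(), sentence = character(),
                  problem = character()))
  }
  bind_rows(bad)
}

#' Write / read planted ground truth as JSON lines
#'
#' One JSON object per planted instance, fields mirroring the ground-truth
#' tibble.
#'
#' @param truth Ground-truth tibble.
#' @param path File path.
#' @return `path` (write) or the tibble (read).
#' @export
write_ground_truth <- function(truth, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(truth))) {
    writeLines(jsonlite::toJSON(as.list(truth[i, ]), auto_unbox = TRUE,
                                na = "null"),
               con, useBytes = TRUE)
  }
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- lapply(lines, function(ln) {
    x <- jsonlite::fromJSON(ln)
    x <- lapply(x, function(v) if (is.null(v)) NA else v)
    as_tibble(x)
  })
  out <- bind_rows(rows)
  for (col in c("start_idx", "end_idx", "start2_idx", "end2_idx",
                "removal_idx")) {
    if (col %in% names(out)) out[[col]] <- as.integer(out[[col]])
  }
  for (col in c("label", "sentence", "sentence2", "database", "entry",
                "database2", "entry2")) {
    if (col %in% names(out)) out[[col]] <- as.character(out[[col]])
  }
  out
}
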