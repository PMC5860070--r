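#' Build the sentence occurrence index of a corpus
#'
#' Extracts the normalized sentences of every entry version and links each
#' sentence to its (database, entry, release) slots. The index is the backbone
#' of every reuse measure and pattern detector: it stores, for each
#' (database, entry, release, sentence), the number of slots the sentence
#' fills in that entry's text (within-entry duplicates counted), together with
#' the source release timelines. Totals and multiplicities count slots;
#' presence over time (for run computation) is the binary support of the map.
#'
#' @param corpus A [versioned_corpus()].
#' @param splitter Sentence splitter passed to [extract_sentences()].
#' @param min_chars Minimum sentence length passed to [extract_sentences()].
#' @return An `occurrence_index` object: tibbles `occurrences` (`database`,
#'   `entry`, `release`, `ordinal`, `sentence`, `slots`) and `timelines`
#'   (`database`, `release`, `ordinal`, `date`), plus the grouping vector.
#' @examples
#' corp <- versioned_corpus(
#'   entries = tibble::tibble(database = "D", release = "r1", entry = "A",
#'                            text = "Binds DNA. Binds DNA. Required for vision."),
#'   timelines = tibble::tibble(database = "D", release = "r1", date = "2001-01-01"))
#' idx <- build_index(corp)
#' sentence_multiplicity(idx, "D", "r1", "binds dna.")
#' @export
build_index <- function(corpus, splitter = split_sentences, min_chars = 0L) {
  stopifnot(inherits(corpus, "versioned_corpus"))
  en <- corpus$entries
  sent <- lapply(en$text, extract_sentences, splitter = splitter,
                 min_chars = min_chars)
  nper <- lengths(sent)
  occ <- tibble(
    database = rep(en$database, nper),
    entry = rep(en$entry, nper),
    release = rep(en$release, nper),
    sentence = unlist(sent, use.names = FALSE) %||% character(0)
  )
  occ <- occ %>%
    count(.data$database, .data$entry, .data$release, .data$sentence,
          name = "slots") %>%
    left_join(select(corpus$timelines, "database", "release", "ordinal"),
              by = c("database", "release")) %>%
    arrange(.data$database, .data$entry, .data$ordinal, .data$sentence) %>%
    select("database", "entry", "release", "ordinal", "sentence", "slots")
  occurrence_index(occ, corpus$timelines, corpus$grouping)
}

#' Low-level occurrence index constructor
#'
#' Assembles an index directly from an occurrence table and timelines,
#' checking referential integrity. [build_index()] is the normal entry point;
#' this constructor exists for tests, oracles and deserialization.
#'
#' @param occurrences Tibble with columns `database`, `entry`, `release`,
#'   `ordinal`, `sentence`, `slots`.
#' @param timelines Tibble with columns `database`, `release`, `ordinal`,
#'   `date`.
#' @param grouping Named character vector database -> group label; defaults to
#'   identity.
#' @return An `occurrence_index`.
#' @export
occurrence_index <- function(occurrences, timelines, grouping = NULL) {
  occurrences <- as_tibble(occurrences)
  timelines <- as_tibble(timelines)
  known <- paste(timelines$database, timelines$release, sep = "\r")
  ref <- paste(occurrences$database, occurrences$release, sep = "\r")
  if (any(!(ref %in% known))) {
    abort("Occurrence references a release absent from the timelines.")
  }
  if (nrow(occurrences) && any(occurrences$slots < 1L)) {
    abort("Occurrence slot counts must be >= 1.")
  }
  dbs <- unique(timelines$database)
  if (is.null(grouping)) grouping <- stats::setNames(dbs, dbs)
  structure(list(occurrences = occurrences, timelines = timelines,
                 grouping = grouping),
            class = "occurrence_index")
}

#' @export
print.occurrence_index <- function(x, ...) {
  cat("<occurrence_index>\n")
  cat("  databases:   ", paste(unique(x$timelines$database), collapse = ", "),
      "\n", sep = "")
  cat("  occurrences: ", nrow(x$occurrences), "\n", sep = "")
  cat("  sentences:   ", dplyr::n_distinct(x$occurrences$sentence), "\n",
      sep = "")
  invisible(x)
}

#' @export
#' @method tidy occurrence_index
tidy.occurrence_index <- function(x, ...) x$occurrences

#' @export
#' @method glance occurrence_index
glance.occurrence_index <- function(x, ...) {
  tibble(n_databases = dplyr::n_distinct(x$timelines$database),
         n_releases = nrow(x$timelines),
         n_sentences = dplyr::n_distinct(x$occurrences$sentence),
         n_occurrences = nrow(x$occurrences),
         total_slots = sum(x$occurrences$slots))
}

check_database <- function(index, database) {
  if (!database %in% index$timelines$database) {
    abort(paste0("Unknown database: '", database, "'."))
  }
  invisible(database)
}

check_release <- function(index, database, release) {
  check_database(index, database)
  tl <- index$timelines
  if (!any(tl$database == database & tl$release == release)) {
    abort(paste0("Unknown release '", release, "' of database '", database,
                 "'."))
  }
  invisible(release)
}

n_releases_of <- function(index, database) {
  sum(index$timelines$database == database)
}

#' Occurrences of a sentence
#'
#' Exact support set of a sentence in the index, optionally restricted to one
#' database. The sentence may be given raw (it is normalized first).
#'
#' @param index An `occurrence_index`.
#' @param sentence Sentence string, raw or already normalized.
#' @param database Optional database identifier; `NULL` queries all.
#' @return Tibble of occurrences (possibly zero rows for an unseen sentence).
#' @export
occurrences_of <- function(index, sentence, database = NULL) {
  stopifnot(inherits(index, "occurrence_index"))
  key <- normalize_sentence(sentence)
  occ <- index$occurrences
  if (!is.null(database)) {
    check_database(index, database)
    occ <- filter(occ, .data$database == !!database)
  }
  filter(occ, .data$sentence == key)
}

#' Per-release multiplicity of a sentence
#'
#' Number of entry-slots containing the sentence at one release of one
#' database, counting within-entry duplicates. Summed over all sentences of a
#' release this reproduces the release's total sentence count (conservation).
#'
#' @inheritParams occurrences_of
#' @param database Database identifier.
#' @param release Release identifier.
#' @return A non-negative integer count.
#' @export
sentence_multiplicity <- function(index, database, release, sentence) {
  stopifnot(inherits(index, "occurrence_index"))
  check_release(index, database, release)
  key <- normalize_sentence(sentence)
  occ <- index$occurrences
  sum(occ$slots[occ$database == database & occ$release == release &
                  occ$sentence == key])
}

# All maximal presence runs of a database, one row per (entry, sentence, run).
# Presence is binary per release; a run is a maximal contiguous ordinal span.
runs_of_database <- function(index, database) {
  occ <- index$occurrences
  occ <- occ[occ$database == database,
             c("entry", "sentence", "ordinal"), drop = FALSE]
  nrel <- n_releases_of(index, database)
  if (!nrow(occ)) {
    return(tibble(database = character(), entry = character(),
                  sentence = character(), start_idx = integer(),
                  end_idx = integer(), censored = logical()))
  }
  occ <- occ[!duplicated(occ), ]
  o <- order(occ$entry, occ$sentence, occ$ordinal)
  ent <- occ$entry[o]; sen <- occ$sentence[o]; ord <- occ$ordinal[o]
  new_pair <- c(TRUE, ent[-1] != ent[-length(ent)] |
                  sen[-1] != sen[-length(sen)])
  # a new run starts at a new (entry, sentence) pair or an ordinal gap
  gap <- c(TRUE, ord[-1] != ord[-length(ord)] + 1L)
  run_id <- cumsum(new_pair | gap)
  start_idx <- ord[!duplicated(run_id)]
  last <- rev(!duplicated(rev(run_id)))
  end_idx <- ord[last]
  tibble(database = database, entry = ent[!duplicated(run_id)],
         sentence = sen[!duplicated(run_id)],
         start_idx = start_idx, end_idx = end_idx,
         censored = end_idx == nrel)
}

#' Maximal presence runs of a sentence in one entry
#'
#' A presence run is a maximal contiguous interval of releases (by timeline
#' ordinal) during which the sentence sits in the entry's annotation. Runs are
#' the substrate of pattern detection: a length-1 uncensored run is the
#' transient signature, a censored run touches the database's latest release
#' and its future is unobservable.
#'
#' @inheritParams occurrences_of
#' @param database Database identifier.
#' @param entry Entry identifier.
#' @return Tibble with columns `database`, `entry`, `sentence`, `start_idx`,
#'   `end_idx` (1-based release ordinals) and `censored`; zero rows if the
#'   sentence never occurs in the entry.
#' @export
presence_runs <- function(index, sentence, database, entry) {
  stopifnot(inherits(index, "occurrence_index"))
  check_database(index, database)
  key <- normalize_sentence(sentence)
  runs <- runs_of_database(index, database)
  filter(runs, .data$sentence == key, .data$entry == !!entry) %>%
    arrange(.data$start_idx)
}

#' Persist an occurrence index to a flat file
#'
#' Writes release records (`R <tab> database <tab> release <tab> ordinal
#' <tab> date`), occurrence records (`O <tab> database <tab> entry <tab>
#' release <tab> ordinal <tab> slots <tab> sentence`) and grouping records
#' (`G <tab> database <tab> group`), sorted deterministically. The store is a
#' plain diff-friendly text file; queries against a re-read index are exact
#' and identical to the original.
#'
#' @param index An `occurrence_index`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "occurrence_index"))
  tl <- index$timelines
  rlines <- paste("R", tl$database, tl$release, tl$ordinal,
                  format(tl$date, "%Y-%m-%d"), sep = "\t")
  occ <- arrange(index$occurrences, .data$database, .data$entry,
                 .data$ordinal, .data$sentence)
  olines <- if (nrow(occ)) {
    paste("O", occ$database, occ$entry, occ$release, occ$ordinal, occ$slots,
          escape_text(occ$sentence), sep = "\t")
  } else character(0)
  grp <- index$grouping
  glines <- paste("G", names(grp), unname(grp), sep = "\t")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(rlines, glines, olines), con, useBytes = TRUE)
  invisible(path)
}

#' Read an occurrence index from its flat-file store
#'
#' @param path Path written by [write_index()].
#' @return An `occurrence_index`.
#' @export
read_index <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  kind <- substr(lines, 1, 1)
  parse_block <- function(k, nf) {
    sel <- lines[kind == k]
    if (!length(sel)) return(NULL)
    do.call(rbind, strsplit(sel, "\t", fixed = TRUE))
  }
  rm_ <- parse_block("R")
  if (is.null(rm_)) abort("Index file contains no release records.")
  timelines <- tibble(database = rm_[, 2], release = rm_[, 3],
                      ordinal = as.integer(rm_[, 4]),
                      date = as.Date(rm_[, 5]))
  om <- parse_block("O")
  occurrences <- if (is.null(om)) {
    tibble(database = character(), entry = character(), release = character(),
           ordinal = integer(), sentence = character(), slots = integer())
  } else {
    tibble(database = om[, 2], entry = om[, 3], release = om[, 4],
           ordinal = as.integer(om[, 5]), slots = as.integer(om[, 6]),
           sentence = unescape_text(om[, 7]))[, c("database", "entry",
                                                  "release", "ordinal",
                                                  "sentence", "slots")]
  }
  gm <- parse_block("G")
  grouping <- if (is.null(gm)) NULL else stats::setNames(gm[, 3], gm[, 2])
  occurrence_index(occurrences, timelines, grouping)
}
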