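#' Detect the transient pattern in one database
#'
#' A sentence is transient if, in at least one entry, it is present for
#' exactly one release and then removed — a maximal presence run of length 1
#' that does not touch the database's latest release. Runs touching the
#' latest release are censored: a sentence seen only in the current version
#' cannot be classified as transient (see
#' [detect_possibly_transient()]). Counting is sentence-level: a sentence
#' needs to exhibit the pattern in a single entry to be labeled, and it is
#' labeled at most once per database, witnessed by its earliest qualifying
#' run.
#'
#' @param index An `occurrence_index`.
#' @param database Database identifier; must have at least 2 releases
#'   (transience is unobservable in a single-release database).
#' @return Tibble with one row per transient sentence: `label`, `sentence`,
#'   `database`, `entry` (witness), `start_idx`, `end_idx`.
#' @export
detect_transient <- function(index, database) {
  stopifnot(inherits(index, "occurrence_index"))
  check_database(index, database)
  if (n_releases_of(index, database) < 2L) {
    abort(paste0("Database '", database, "' has a single release; ",
                 "transience is unobservable."))
  }
  runs <- runs_of_database(index, database)
  hits <- runs[runs$start_idx == runs$end_idx & !runs$censored, ]
  witness_per_sentence(hits, "transient")
}

#' Detect the possibly-transient pattern in one database
#'
#' A sentence is possibly transient if it is new in the database's latest
#' release for some entry — a censored presence run of length 1 — so its
#' removal or persistence cannot yet be observed. Not a pattern in its own
#' right but the unclassifiable remainder of transience; accordingly a
#' sentence already labeled transient elsewhere in the database is not also
#' labeled possibly transient (transient takes precedence).
#'
#' @inheritParams detect_transient
#' @param database Database identifier (single-release databases are legal:
#'   every sentence there is new in the latest release).
#' @return Tibble as in [detect_transient()] with `label =
#'   "possibly_transient"`.
#' @export
detect_possibly_transient <- function(index, database) {
  stopifnot(inherits(index, "occurrence_index"))
  check_database(index, database)
  runs <- runs_of_database(index, database)
  hits <- runs[runs$start_idx == runs$end_idx & runs$censored, ]
  transient <- unique(runs$sentence[runs$start_idx == runs$end_idx &
                                      !runs$censored])
  hits <- hits[!(hits$sentence %in% transient), ]
  witness_per_sentence(hits, "possibly_transient")
}

# one evidence row per sentence: earliest qualifying run, ties by entry
witness_per_sentence <- function(hits, label) {
  if (!nrow(hits)) {
    return(tibble(label = character(), sentence = character(),
                  database = character(), entry = character(),
                  start_idx = integer(), end_idx = integer()))
  }
  hits %>%
    arrange(.data$sentence, .data$start_idx, .data$entry) %>%
    group_by(.data$sentence) %>%
    slice(1) %>%
    ungroup() %>%
    mutate(label = label) %>%
    select("label", "sentence", "database", "entry", "start_idx", "end_idx") %>%
    arrange(.data$sentence)
}

#' Detect the missing-origin pattern in one database
#'
#' A sentence follows the missing-origin pattern when it debuts in an origin
#' entry (or several simultaneously), is later propagated to one or more
#' secondary entries, and is then removed from the origin while still
#' remaining in at least one secondary — the signature of an update that
#' failed to percolate to the copies.
#'
#' Operationally, with `f` the earliest release ordinal at which the sentence
#' occurs anywhere in the database and `O` the set of entries carrying it at
#' `f` (the origin set; simultaneous debuts share origin status), the label
#' fires if some release ordinal `m > f` exists where (i) no origin entry
#' carries the sentence, (ii) at least one origin entry carried it at `m - 1`,
#' and (iii) at least one entry outside `O`, whose own first occurrence is
#' strictly after `f`, carries it at `m`. Only the first qualifying removal
#' `m` is witnessed; later reintroductions do not retract the label. A
#' secondary debuting exactly at `m` still counts (propagation and removal
#' observed at the same release).
#'
#' @inheritParams detect_transient
#' @param database Database identifier; must have at least 3 releases
#'   (debut, propagation and removal need three observation points).
#' @return Tibble with one row per missing-origin sentence: `label`,
#'   `sentence`, `database`, `first_idx` (debut ordinal `f`),
#'   `origin_entries` and `surviving_entries` (list columns),
#'   `removal_idx` (`m`) and `removal_release`.
#' @export
detect_missing_origin <- function(index, database) {
  stopifnot(inherits(index, "occurrence_index"))
  check_database(index, database)
  nrel <- n_releases_of(index, database)
  if (nrel < 3L) {
    abort(paste0("Database '", database, "' has fewer than 3 releases; ",
                 "the missing-origin pattern needs debut, propagation and ",
                 "removal to be observable."))
  }
  occ <- index$occurrences
  occ <- occ[occ$database == database, c("entry", "sentence", "ordinal")]
  occ <- occ[!duplicated(occ), ]
  empty <- tibble(label = character(), sentence = character(),
                  database = character(), first_idx = integer(),
                  origin_entries = list(), surviving_entries = list(),
                  removal_idx = integer(), removal_release = character())
  if (!nrow(occ)) return(empty)
  tl <- index$timelines[index$timelines$database == database, ]
  rel_of <- stats::setNames(tl$release, tl$ordinal)
  out <- list()
  by_sentence <- split(occ[c("entry", "ordinal")], occ$sentence)
  for (s in names(by_sentence)) {
    chunk <- by_sentence[[s]]
    f <- min(chunk$ordinal)
    origin <- unique(chunk$entry[chunk$ordinal == f])
    others <- setdiff(unique(chunk$entry), origin)
    if (!length(others)) next
    # entries outside the debut set necessarily first occur after f
    o_ord <- chunk$ordinal[chunk$entry %in% origin]
    s_ord <- chunk$ordinal[chunk$entry %in% others]
    found <- NA_integer_
    for (m in (f + 1L):nrel) {
      if (!any(o_ord == m) && any(o_ord == m - 1L) && any(s_ord == m)) {
        found <- m
        break
      }
    }
    if (is.na(found)) next
    survivors <- sort(unique(chunk$entry[chunk$entry %in% others &
                                           chunk$ordinal == found]))
    out[[length(out) + 1L]] <- tibble(
      label = "missing_origin",
      sentence = s,
      database = database, first_idx = f,
      origin_entries = list(sort(origin)),
      surviving_entries = list(survivors),
      removal_idx = found,
      removal_release = unname(rel_of[as.character(found)]))
  }
  if (!length(out)) return(empty)
  arrange(bind_rows(out), .data$sentence)
}

#' Summarize pattern counts for one or all databases
#'
#' Counts of distinct sentences per label — missing origin, transient,
#' possibly transient — under the precedence rule (a sentence both transient
#' and new-in-latest counts as transient only). Databases with fewer releases
#' than a detector requires propagate that detector's error.
#'
#' @param index An `occurrence_index`.
#' @param database Optional database identifier; `NULL` summarizes every
#'   database in the index.
#' @return Tibble with columns `database`, `missing_origin`, `transient`,
#'   `possibly_transient`.
#' @export
pattern_summary <- function(index, database = NULL) {
  stopifnot(inherits(index, "occurrence_index"))
  dbs <- if (is.null(database)) unique(index$timelines$database) else database
  rows <- lapply(dbs, function(db) {
    tibble(database = db,
           missing_origin = nrow(detect_missing_origin(index, db)),
           transient = nrow(detect_transient(index, db)),
           possibly_transient = nrow(detect_possibly_transient(index, db)))
  })
  bind_rows(rows)
}

#' Export pattern evidence and summary reports
#'
#' Writes the summary as TSV (`database`, `missing_origin`, `transient`,
#' `possibly_transient`) and, optionally, one JSON object per evidence row
#' (JSON lines) with fields mirroring the detector outputs.
#'
#' @param index An `occurrence_index`.
#' @param summary_path Output TSV path for the summary.
#' @param evidence_path Optional output path for JSON-lines evidence.
#' @param database Optional database filter.
#' @return The summary tibble, invisibly.
#' @export
write_pattern_report <- function(index, summary_path, evidence_path = NULL,
                                 database = NULL) {
  summ <- pattern_summary(index, database)
  readr::write_tsv(summ, summary_path)
  if (!is.null(evidence_path)) {
    dbs <- if (is.null(database)) unique(index$timelines$database) else database
    ev <- list()
    for (db in dbs) {
      ev[[length(ev) + 1L]] <- detect_missing_origin(index, db)
      ev[[length(ev) + 1L]] <- detect_transient(index, db)
      ev[[length(ev) + 1L]] <- detect_possibly_transient(index, db)
    }
    con <- file(evidence_path, open = "wb")
    on.exit(close(con))
    for (tab in ev) {
      if (!nrow(tab)) next
      for (i in seq_len(nrow(tab))) {
        writeLines(jsonlite::toJSON(as.list(tab[i, ]), auto_unbox = TRUE,
                                    dataframe = "rows"),
                   con, useBytes = TRUE)
      }
    }
  }
  invisible(summ)
}
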