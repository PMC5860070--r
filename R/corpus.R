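#' Construct a versioned annotation corpus
#'
#' A versioned corpus holds, for a set of databases, (i) each database's
#' release timeline — the ordered, dated sequence of published snapshots — and
#' (ii) one plain-text annotation block per entry per release. Releases are
#' ordered by their position in the timeline (dates may tie and are used only
#' for cross-database work, where they bound when a sentence can have
#' appeared: a record's date is the date of the release carrying it, an upper
#' bound whose slack is the release frequency). An entry absent from a release
#' — deleted or not yet created — simply has no record there; absence is
#' removal, there are no tombstones.
#'
#' @param entries Tibble/data frame with columns `database`, `release`,
#'   `entry`, `text` (plain text, markup already stripped by adapters). One
#'   row per entry per release; `(database, release, entry)` must be unique.
#' @param timelines Tibble/data frame with columns `database`, `release`,
#'   `date` (coercible with [as.Date()]). Within a database, releases must be
#'   unique and dates non-decreasing in row order.
#' @param grouping Optional named character vector mapping each database to a
#'   group label (e.g. collapsing Swiss-Prot and TrEMBL into "UniProtKB") for
#'   cross-database analysis; defaults to each database being its own group.
#' @return An object of class `versioned_corpus`: a list with tibbles
#'   `timelines` (database, release, ordinal, date) and `entries`, plus the
#'   grouping vector.
#' @seealso [read_corpus()], [write_corpus()], [build_index()]
#' @export
versioned_corpus <- function(entries, timelines, grouping = NULL) {
  timelines <- as_tibble(timelines)[, c("database", "release", "date")]
  timelines$database <- as.character(timelines$database)
  timelines$release <- as.character(timelines$release)
  timelines$date <- as.Date(timelines$date)
  entries <- as_tibble(entries)
  if (!nrow(entries)) {
    entries <- tibble(database = character(), release = character(),
                      entry = character(), text = character())
  }
  entries <- entries[, c("database", "release", "entry", "text")]
  for (col in names(entries)) entries[[col]] <- as.character(entries[[col]])

  validate_timelines(timelines)
  timelines <- timelines %>%
    group_by(.data$database) %>%
    mutate(ordinal = row_number()) %>%
    ungroup() %>%
    select("database", "release", "ordinal", "date")

  validate_entries(entries, timelines)
  dbs <- unique(timelines$database)
  if (is.null(grouping)) grouping <- stats::setNames(dbs, dbs)
  missing_grp <- setdiff(unique(entries$database), names(grouping))
  if (length(missing_grp)) {
    abort(paste0("No group assigned for database(s): ",
                 paste(missing_grp, collapse = ", ")))
  }
  structure(list(timelines = timelines, entries = entries,
                 grouping = grouping),
            class = "versioned_corpus")
}

validate_timelines <- function(timelines) {
  if (anyNA(timelines$date)) abort("Timeline dates must be valid dates.")
  by_db <- split(timelines, timelines$database)
  for (tl in by_db) {
    if (anyDuplicated(tl$release)) {
      abort(paste0("Duplicate release ids in timeline of database '",
                   tl$database[1], "'."))
    }
    if (is.unsorted(tl$date)) {
      abort(paste0("Timeline dates of database '", tl$database[1],
                   "' must be non-decreasing."))
    }
  }
  invisible(timelines)
}

validate_entries <- function(entries, timelines) {
  if (!nrow(entries)) return(invisible(entries))
  if (any(!nzchar(entries$entry))) abort("Entry ids must be non-empty.")
  key <- paste(entries$database, entries$release, entries$entry, sep = "\r")
  if (anyDuplicated(key)) {
    abort("Duplicate (database, release, entry) records in corpus.")
  }
  known <- paste(timelines$database, timelines$release, sep = "\r")
  ref <- paste(entries$database, entries$release, sep = "\r")
  bad <- !(ref %in% known)
  if (any(bad)) {
    i <- which(bad)[1]
    abort(paste0("Entry '", entries$entry[i], "' references release '",
                 entries$release[i], "' absent from the timeline of database '",
                 entries$database[i], "'."))
  }
  invisible(entries)
}

#' @export
print.versioned_corpus <- function(x, ...) {
  cat("<versioned_corpus>\n")
  cat("  databases: ", paste(unique(x$timelines$database), collapse = ", "),
      "\n", sep = "")
  cat("  releases:  ", nrow(x$timelines), "\n", sep = "")
  cat("  entry versions: ", nrow(x$entries), "\n", sep = "")
  invisible(x)
}

#' @export
#' @method tidy versioned_corpus
tidy.versioned_corpus <- function(x, ...) x$entries

#' @export
#' @method glance versioned_corpus
glance.versioned_corpus <- function(x, ...) {
  tibble(n_databases = dplyr::n_distinct(x$timelines$database),
         n_releases = nrow(x$timelines),
         n_entry_versions = nrow(x$entries),
         n_entries = dplyr::n_distinct(paste(x$entries$database,
                                             x$entries$entry)))
}

escape_text <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

unescape_text <- function(x) {
  # sentinel guards escaped backslashes while \t / \n are expanded
  x <- gsub("\\\\", "\x01\x02", x, fixed = TRUE)
  x <- gsub("\\t", "\t", x, fixed = TRUE)
  x <- gsub("\\n", "\n", x, fixed = TRUE)
  gsub("\x01\x02", "\\", x, fixed = TRUE)
}

#' Read a corpus from the canonical line-delimited format
#'
#' The canonical format is UTF-8 text with one record per line, two kinds:
#' timeline records `T <tab> database <tab> release <tab> ISO-8601 date` and
#' entry records `E <tab> database <tab> release <tab> entry <tab> text`
#' (tabs, newlines and backslashes in text escaped as `\\t`, `\\n`, `\\\\`).
#' A JSON-lines dialect is accepted interchangeably: objects with keys
#' `database`/`release`/`date` (timeline) or `database`/`release`/`entry`/
#' `text` (entry). Record order in the file is irrelevant to the result;
#' timeline order within a database is preserved as written.
#'
#' @param path Path to a canonical corpus file.
#' @param grouping Optional database-to-group mapping passed to
#'   [versioned_corpus()].
#' @return A [versioned_corpus()] object.
#' @export
read_corpus <- function(path, grouping = NULL) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) && startsWith(trimws(lines[1]), "{")) {
    return(read_corpus_jsonl(lines, lineno, grouping))
  }
  tl <- list(); en <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (f[1] == "T" && length(f) == 4L) {
      tl[[length(tl) + 1L]] <- f[-1]
    } else if (f[1] == "E" && (length(f) == 5L || length(f) == 4L)) {
      if (length(f) == 4L) f <- c(f, "")  # empty text field
      en[[length(en) + 1L]] <- f[-1]
    } else {
      abort(paste0("Malformed corpus record at line ", lineno[i], "."))
    }
  }
  timelines <- if (length(tl)) {
    m <- do.call(rbind, tl)
    tibble(database = m[, 1], release = m[, 2], date = as.Date(m[, 3]))
  } else {
    tibble(database = character(), release = character(), date = as.Date(character()))
  }
  entries <- if (length(en)) {
    m <- do.call(rbind, en)
    tibble(database = m[, 1], release = m[, 2], entry = m[, 3],
           text = unescape_text(m[, 4]))
  } else {
    tibble(database = character(), release = character(),
           entry = character(), text = character())
  }
  versioned_corpus(entries, timelines, grouping)
}

read_corpus_jsonl <- function(lines, lineno, grouping) {
  tl <- list(); en <- list()
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$database) || is.null(rec$release)) {
      abort(paste0("Malformed corpus record at line ", lineno[i], "."))
    }
    if (!is.null(rec$entry)) {
      en[[length(en) + 1L]] <- tibble(database = rec$database,
                                      release = rec$release,
                                      entry = rec$entry,
                                      text = rec$text %||% "")
    } else if (!is.null(rec$date)) {
      tl[[length(tl) + 1L]] <- tibble(database = rec$database,
                                      release = rec$release,
                                      date = as.Date(rec$date))
    } else {
      abort(paste0("Malformed corpus record at line ", lineno[i], "."))
    }
  }
  versioned_corpus(bind_rows(en), bind_rows(tl), grouping)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a corpus in the canonical line-delimited format
#'
#' Timeline records come first (in timeline order), then entry records sorted
#' by (database, release ordinal, entry) so two writes of the same corpus are
#' byte-identical and the output diffs cleanly.
#'
#' @param corpus A [versioned_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "versioned_corpus"))
  tl <- corpus$timelines
  tlines <- paste("T", tl$database, tl$release, format(tl$date, "%Y-%m-%d"),
                  sep = "\t")
  en <- corpus$entries %>%
    left_join(select(tl, "database", "release", "ordinal"),
              by = c("database", "release")) %>%
    arrange(.data$database, .data$ordinal, .data$entry)
  elines <- if (nrow(en)) {
    paste("E", en$database, en$release, en$entry, escape_text(en$text),
          sep = "\t")
  } else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(tlines, elines), con, useBytes = TRUE)
  invisible(path)
}

#' Read a database-to-group mapping from a config file
#'
#' Accepts YAML (`database: group` mappings) or flat `database=group` /
#' `database<TAB>group` lines; `#` comments and blank lines are ignored in the
#' flat form. Grouping collapses related databases (e.g. Swiss-Prot and TrEMBL
#' into UniProtKB) for cross-database analysis.
#'
#' @param path Path to the config file.
#' @return Named character vector, names are databases, values group labels.
#' @export
read_grouping <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  if (grepl("\\.ya?ml$", path)) {
    x <- yaml::read_yaml(path)
    return(vapply(x, as.character, character(1)))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- character(0)
  for (ln in lines) {
    f <- strsplit(ln, "[=\t]", perl = TRUE)[[1]]
    if (length(f) != 2L) abort(paste0("Malformed grouping line: ", ln))
    out[trimws(f[1])] <- trimws(f[2])
  }
  out
}
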