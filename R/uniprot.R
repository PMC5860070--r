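#' Parse CC comment blocks from a UniProtKB-style DAT flat file
#'
#' Harvests the free-text comment annotation of a UniProtKB flat file into
#' entry records suitable for a [versioned_corpus()]. Entries are delimited by
#' a terminator line (`//`); the accession is the first accession on the first
#' `AC` line; comment text lives on `CC` lines, each topic starting with
#' `-!- TOPIC:` and continuing on indented `CC` lines. For example the lines
#'
#' \preformatted{CC   -!- FUNCTION: May be a transcription factor with important functions
#' CC       in eye and nasal development.}
#'
#' become the text
#' `"May be a transcription factor with important functions in eye and nasal development."`
#'
#' Line-prefix markup (`CC`, `-!- TOPIC:`) is removed and continuation lines
#' are joined with single spaces; successive topic blocks are separated by a
#' blank line so the sentence splitter can never fuse sentences across topics
#' (topics are independent statements). Database-specific formatting removal
#' is the adapter's job: the canonical corpus carries plain text only.
#' Standard non-topic CC furniture (copyright banners, `---` rules) is
#' ignored. Entries with no CC text are emitted with empty text; entries with
#' no AC line are skipped with a warning.
#'
#' @param input Path to a DAT file, or a character vector of its lines.
#' @param database Database identifier to stamp on every record.
#' @param release Release identifier to stamp on every record.
#' @param topics Optional character vector of topic names (e.g. `"FUNCTION"`)
#'   to harvest; `NULL` (default) harvests all CC topics.
#' @return Tibble with columns `database`, `release`, `entry`, `text` — one
#'   row per entry, in file order.
#' @export
parse_uniprot_dat <- function(input, database, release, topics = NULL) {
  lines <- if (length(input) == 1L && file.exists(input)) {
    readLines(input, warn = FALSE)
  } else {
    input
  }
  out <- list()
  acc <- NULL
  cc_topics <- list()   # list of character vectors, one per topic block
  cur_topic <- NULL
  cur_lines <- character(0)
  in_entry <- FALSE

  flush_topic <- function() {
    if (!is.null(cur_topic) && length(cur_lines)) {
      if (is.null(topics) || cur_topic %in% topics) {
        cc_topics[[length(cc_topics) + 1L]] <<-
          paste(trimws(cur_lines), collapse = " ")
      }
    }
    cur_topic <<- NULL
    cur_lines <<- character(0)
  }
  flush_entry <- function() {
    flush_topic()
    if (is.null(acc)) {
      if (in_entry) warning("DAT entry without AC line skipped.", call. = FALSE)
    } else {
      out[[length(out) + 1L]] <<- tibble(
        database = database, release = release, entry = acc,
        text = paste(unlist(cc_topics), collapse = "\n\n"))
    }
    acc <<- NULL
    cc_topics <<- list()
    in_entry <<- FALSE
  }

  for (ln in lines) {
    tag <- substr(ln, 1, 2)
    if (trimws(ln) == "//") { flush_entry(); next }
    if (!nzchar(trimws(ln))) next
    in_entry <- TRUE
    if (tag == "AC" && is.null(acc)) {
      first <- strsplit(trimws(substr(ln, 6, nchar(ln))), ";", fixed = TRUE)[[1]][1]
      acc <- trimws(first)
    } else if (tag == "CC") {
      body <- substr(ln, 6, nchar(ln))
      if (grepl("^\\s*-!-", body)) {
        flush_topic()
        rest <- sub("^\\s*-!-\\s*", "", body)
        colon <- regexpr(":", rest, fixed = TRUE)
        if (colon > 0) {
          cur_topic <- trimws(substr(rest, 1, colon - 1L))
          cur_lines <- trimws(substr(rest, colon + 1L, nchar(rest)))
          cur_lines <- cur_lines[nzchar(cur_lines)]
        } else {
          cur_topic <- trimws(rest)
        }
      } else if (grepl("^\\s*-{5,}", body) || !nzchar(trimws(body))) {
        # copyright rules / banners between topics: end any open topic
        flush_topic()
      } else if (!is.null(cur_topic)) {
        cur_lines <- c(cur_lines, body)
      }
    }
  }
  if (in_entry || !is.null(acc)) {
    abort("Truncated DAT stream: final entry lacks '//' terminator.")
  }
  if (!length(out)) {
    return(tibble(database = character(), release = character(),
                  entry = character(), text = character()))
  }
  bind_rows(out)
}
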