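#' Presence timeline matrix of a sentence
#'
#' The per-sentence view behind propagation-pattern figures: rows are the
#' entries (qualified by database) that ever carried the sentence, columns
#' are releases in date order, cells are presence flags. An unseen sentence
#' yields a zero-row matrix. This is the exportable data that an interactive
#' timeline chart would plot.
#'
#' @param indexes An `occurrence_index` or a list of them.
#' @param sentence Sentence, raw text or normalized key (normalized
#'   internally, so text pasted from a database record works).
#' @param databases Optional character vector restricting the databases
#'   considered.
#' @return A `timeline_matrix`: list with `sentence`, `releases` (tibble
#'   `database`, `release`, `ordinal`, `date`), `entries` (tibble `database`,
#'   `entry`) and `cells`, a logical matrix entries x releases.
#' @export
timeline_matrix <- function(indexes, sentence, databases = NULL) {
  indexes <- as_index_list(indexes)
  key <- normalize_sentence(sentence)
  tl <- bind_rows(lapply(indexes, function(ix) ix$timelines))
  occ <- bind_rows(lapply(indexes, function(ix) {
    distinct(ix$occurrences, .data$database, .data$entry, .data$release,
             .data$ordinal, .data$sentence)
  }))
  if (!is.null(databases)) {
    tl <- filter(tl, .data$database %in% databases)
    occ <- filter(occ, .data$database %in% databases)
  }
  occ <- filter(occ, .data$sentence == key)
  releases <- arrange(tl, .data$date, .data$database, .data$ordinal)
  ents <- distinct(occ, .data$database, .data$entry) %>%
    arrange(.data$database, .data$entry)
  cells <- matrix(FALSE, nrow = nrow(ents), ncol = nrow(releases),
                  dimnames = list(
                    if (nrow(ents)) paste(ents$database, ents$entry, sep = ":")
                    else NULL,
                    paste(releases$database, releases$release, sep = ":")))
  if (nrow(occ)) {
    ri <- match(paste(occ$database, occ$entry),
                paste(ents$database, ents$entry))
    ci <- match(paste(occ$database, occ$release),
                paste(releases$database, releases$release))
    cells[cbind(ri, ci)] <- TRUE
  }
  structure(list(sentence = key, releases = releases, entries = ents,
                 cells = cells),
            class = "timeline_matrix")
}

#' @export
print.timeline_matrix <- function(x, ...) {
  cat("<timeline_matrix> sentence: ", substr(x$sentence, 1, 60),
      if (nchar(x$sentence) > 60) "..." else "", "\n", sep = "")
  cat("  ", nrow(x$entries), " entries x ", nrow(x$releases), " releases\n",
      sep = "")
  invisible(x)
}

#' @export
#' @method tidy timeline_matrix
tidy.timeline_matrix <- function(x, ...) {
  if (!nrow(x$entries)) {
    return(tibble(database = character(), entry = character(),
                  release = character(), date = as.Date(character()),
                  present = logical()))
  }
  grid <- tidyr::expand_grid(
    i = seq_len(nrow(x$entries)), j = seq_len(nrow(x$releases)))
  tibble(database = x$entries$database[grid$i],
         entry = x$entries$entry[grid$i],
         release_database = x$releases$database[grid$j],
         release = x$releases$release[grid$j],
         date = x$releases$date[grid$j],
         present = x$cells[cbind(grid$i, grid$j)]) %>%
    filter(.data$database == .data$release_database) %>%
    select(-"release_database")
}

#' Plot a sentence presence timeline
#'
#' Tile plot of the timeline matrix: entries on the vertical axis, release
#' dates on the horizontal, filled tiles where the sentence is present. The
#' missing-origin signature reads directly off the plot: the origin row stops
#' while a secondary row continues.
#'
#' @param object A [timeline_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
#' @method autoplot timeline_matrix
autoplot.timeline_matrix <- function(object, ...) {
  dat <- tidy(object) %>% filter(.data$present)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$date,
                                    y = paste(.data$database, .data$entry,
                                              sep = ":"))) +
    ggplot2::geom_tile(fill = "steelblue",
                       width = 25, height = 0.8) +
    ggplot2::labs(x = "release date", y = NULL,
                  title = substr(object$sentence, 1, 70)) +
    ggplot2::theme_minimal()
}

#' Export a timeline matrix as JSON
#'
#' Writes rows (entries), dated columns and boolean cells as a single JSON
#' object.
#'
#' @param x A [timeline_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timeline_json <- function(x, path) {
  stopifnot(inherits(x, "timeline_matrix"))
  obj <- list(
    sentence = x$sentence,
    rows = if (nrow(x$entries)) {
      lapply(seq_len(nrow(x$entries)), function(i) {
        list(database = x$entries$database[i], entry = x$entries$entry[i])
      })
    } else list(),
    columns = if (nrow(x$releases)) {
      lapply(seq_len(nrow(x$releases)), function(j) {
        list(database = x$releases$database[j],
             release = x$releases$release[j],
             date = format(x$releases$date[j], "%Y-%m-%d"))
      })
    } else list(),
    cells = lapply(seq_len(nrow(x$cells)), function(i) {
      unname(as.logical(x$cells[i, ]))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}
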