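#' Per-release sentence counts
#'
#' For each release the three reuse measures: `total` (every sentence slot,
#' duplicates included — the redundant set), `unique` (distinct sentence
#' strings — the non-redundant set) and `singleton` (strings occurring exactly
#' once in the whole release). Always `singleton <= unique <= total`, and the
#' gap between unique and total is the redundancy mass of the release.
#'
#' @param index An `occurrence_index`.
#' @param database Optional database identifier; `NULL` covers all databases.
#' @param release Optional release identifier (requires `database`); `NULL`
#'   covers all releases of the selected database(s).
#' @return Tibble with columns `database`, `release`, `ordinal`, `date`,
#'   `total`, `unique`, `singleton`, one row per release (releases with no
#'   sentences included, with zero counts).
#' @export
version_counts <- function(index, database = NULL, release = NULL) {
  stopifnot(inherits(index, "occurrence_index"))
  tl <- index$timelines
  if (!is.null(database)) {
    check_database(index, database)
    tl <- filter(tl, .data$database == !!database)
    if (!is.null(release)) {
      check_release(index, database, release)
      tl <- filter(tl, .data$release == !!release)
    }
  } else if (!is.null(release)) {
    abort("`release` requires `database`.")
  }
  per_key <- index$occurrences %>%
    group_by(.data$database, .data$release, .data$sentence) %>%
    summarise(mult = sum(.data$slots), .groups = "drop")
  counts <- per_key %>%
    group_by(.data$database, .data$release) %>%
    summarise(total = sum(.data$mult), unique = n(),
              singleton = sum(.data$mult == 1L), .groups = "drop")
  tl %>%
    left_join(counts, by = c("database", "release")) %>%
    mutate(total = ifelse(is.na(.data$total), 0L, .data$total),
           unique = ifelse(is.na(.data$unique), 0L, .data$unique),
           singleton = ifelse(is.na(.data$singleton), 0L, .data$singleton)) %>%
    arrange(.data$database, .data$ordinal)
}

#' Lifetime unique sentence count of a database
#'
#' Size of the union, over all releases of the database, of the distinct
#' sentence sets — how many different sentence strings the database has ever
#' carried. Always at least the unique count of any single release. Lifetime
#' counts are strictly per database; grouping related databases applies only
#' in cross-database analysis.
#'
#' @param index An `occurrence_index`.
#' @param database Database identifier.
#' @return Integer count.
#' @export
lifetime_unique <- function(index, database) {
  stopifnot(inherits(index, "occurrence_index"))
  check_database(index, database)
  occ <- index$occurrences
  dplyr::n_distinct(occ$sentence[occ$database == database])
}

#' Unique and singleton percentages of a release
#'
#' Percentages of the total sentence count: `unique_pct = 100 * unique /
#' total` and `singleton_pct = 100 * singleton / total`. Reported at full
#' precision; round only at presentation.
#'
#' @param index An `occurrence_index`.
#' @param database Database identifier.
#' @param release Release identifier.
#' @return Tibble with one row: `database`, `release`, `unique_pct`,
#'   `singleton_pct`.
#' @export
reuse_percentages <- function(index, database, release) {
  vc <- version_counts(index, database, release)
  if (vc$total == 0L) {
    abort(paste0("Release '", release, "' of '", database,
                 "' has no sentences; percentages undefined."))
  }
  tibble(database = database, release = release,
         unique_pct = 100 * vc$unique / vc$total,
         singleton_pct = 100 * vc$singleton / vc$total)
}

#' Most reused sentences of a release
#'
#' The `k` sentences with highest multiplicity at one release, in descending
#' multiplicity order with ties broken lexicographically on the sentence key
#' so the ranking is deterministic.
#'
#' @param index An `occurrence_index`.
#' @param database Database identifier.
#' @param release Release identifier.
#' @param k Number of sentences to return (fewer if the release has fewer
#'   distinct sentences).
#' @return Tibble with columns `sentence`, `multiplicity`, at most `k` rows.
#' @export
top_reused <- function(index, database, release, k = 10L) {
  stopifnot(inherits(index, "occurrence_index"))
  check_release(index, database, release)
  if (k < 1L) abort("`k` must be >= 1.")
  occ <- index$occurrences
  occ <- occ[occ$database == database & occ$release == release, ]
  out <- occ %>%
    group_by(.data$sentence) %>%
    summarise(multiplicity = sum(.data$slots), .groups = "drop") %>%
    arrange(desc(.data$multiplicity), .data$sentence)
  utils::head(out, k)
}

#' Write the per-release reuse report
#'
#' Tab-separated table with one row per release: counts and percentages
#' (columns `database`, `release`, `date`, `total`, `unique`, `singleton`,
#' `unique_pct`, `singleton_pct`), the machine-readable form of a per-release
#' reuse summary. Releases with zero sentences get empty percentage fields.
#'
#' @param index An `occurrence_index`.
#' @param path Output TSV path.
#' @param database Optional database filter.
#' @return The report tibble, invisibly.
#' @export
write_reuse_report <- function(index, path, database = NULL) {
  rep <- version_counts(index, database) %>%
    mutate(unique_pct = ifelse(.data$total > 0, 100 * .data$unique / .data$total,
                               NA_real_),
           singleton_pct = ifelse(.data$total > 0,
                                  100 * .data$singleton / .data$total,
                                  NA_real_)) %>%
    select("database", "release", "date", "total", "unique", "singleton",
           "unique_pct", "singleton_pct")
  readr::write_tsv(rep, path)
  invisible(rep)
}

#' Reuse summary bar chart
#'
#' Bar chart of unique and singleton percentages per release with the total
#' sentence count overlaid on a log scale — the standard visual summary of
#' how redundant each database release is.
#'
#' @param counts Output of [version_counts()].
#' @return A ggplot object.
#' @export
plot_reuse <- function(counts) {
  stopifnot(all(c("database", "release", "total", "unique", "singleton") %in%
                  names(counts)))
  dat <- counts %>%
    filter(.data$total > 0) %>%
    mutate(unique_pct = 100 * .data$unique / .data$total,
           singleton_pct = 100 * .data$singleton / .data$total) %>%
    tidyr::pivot_longer(c("unique_pct", "singleton_pct"),
                        names_to = "measure", values_to = "pct")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$release, y = .data$pct,
                                    fill = .data$measure)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~database, scales = "free_x") +
    ggplot2::labs(x = "release", y = "% of total sentences", fill = NULL) +
    ggplot2::theme_minimal()
}
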