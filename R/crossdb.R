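# helpers shared by the cross-database operations ---------------------------

as_index_list <- function(indexes) {
  if (inherits(indexes, "occurrence_index")) return(list(indexes))
  if (is.list(indexes) && length(indexes) &&
      all(vapply(indexes, inherits, logical(1), "occurrence_index"))) {
    return(indexes)
  }
  abort("`indexes` must be an occurrence_index or a list of them.")
}

combined_grouping <- function(indexes, grouping) {
  if (is.null(grouping)) {
    grouping <- unlist(lapply(indexes, function(ix) ix$grouping))
    grouping <- grouping[!duplicated(names(grouping))]
  }
  dbs <- unique(unlist(lapply(indexes, function(ix) ix$timelines$database)))
  missing <- setdiff(dbs, names(grouping))
  if (length(missing)) {
    abort(paste0("Database(s) missing from the grouping map: ",
                 paste(missing, collapse = ", ")))
  }
  grouping
}

#' Partition shared sentences by database-group combination
#'
#' Assigns every sentence that ever occurs in any index (lifetime occurrence,
#' any release) to the exact set of groups in which it occurs, and counts
#' sentences per combination. Lifetime semantics are deliberate: copying
#' between databases spans years and a shared sentence may already be gone
#' from the latest releases. The classes are disjoint by construction, so the
#' counts sum to the size of the union of all groups' lifetime unique sets.
#'
#' @param indexes An `occurrence_index` or a list of them; at least two
#'   groups must remain after grouping.
#' @param grouping Named character vector database -> group label; defaults to
#'   the grouping(s) stored in the indexes. Every database must be mapped.
#' @return Tibble with columns `combination` (semicolon-joined sorted group
#'   labels), `n_groups` and `count`, sorted by count descending then
#'   combination.
#' @export
shared_partition <- function(indexes, grouping = NULL) {
  indexes <- as_index_list(indexes)
  grouping <- combined_grouping(indexes, grouping)
  if (dplyr::n_distinct(grouping) < 2L) {
    abort("shared_partition() needs at least two groups after grouping.")
  }
  occ <- bind_rows(lapply(indexes, function(ix) {
    distinct(ix$occurrences, .data$database, .data$sentence)
  }))
  occ$group <- unname(grouping[occ$database])
  occ <- distinct(occ, .data$group, .data$sentence)
  occ %>%
    group_by(.data$sentence) %>%
    summarise(combination = paste(sort(unique(.data$group)), collapse = "; "),
              n_groups = dplyr::n_distinct(.data$group), .groups = "drop") %>%
    count(.data$combination, .data$n_groups, name = "count") %>%
    arrange(desc(.data$count), .data$combination)
}

#' Release date intervals of a timeline
#'
#' Each release's records are dated by the release itself, so a release date
#' is an upper bound on when its content appeared, with slack equal to the
#' release period. The interval of a release runs from its date to the date
#' of the next release in the same timeline; the latest release's interval is
#' open-ended (`end = NA`). Consecutive intervals abut without overlapping.
#'
#' @param x An `occurrence_index`, [versioned_corpus()] or a timelines tibble
#'   with columns `database`, `release`, `ordinal`, `date`.
#' @param database Optional database filter.
#' @return Tibble with columns `database`, `release`, `ordinal`, `start`,
#'   `end` (both `Date`; `end` `NA` when open).
#' @export
date_intervals <- function(x, database = NULL) {
  tl <- if (inherits(x, "occurrence_index") || inherits(x, "versioned_corpus")) {
    x$timelines
  } else {
    as_tibble(x)
  }
  if (!all(c("database", "release", "ordinal", "date") %in% names(tl))) {
    abort("Timelines must carry database, release, ordinal and date columns.")
  }
  if (anyNA(tl$date)) abort("Timelines lack dates; interval analysis needs them.")
  if (!is.null(database)) tl <- filter(tl, .data$database == !!database)
  tl %>%
    arrange(.data$database, .data$ordinal) %>%
    group_by(.data$database) %>%
    mutate(start = .data$date, end = lead(.data$date)) %>%
    ungroup() %>%
    select("database", "release", "ordinal", "start", "end")
}

#' Search for cross-database missing-origin candidates
#'
#' Within one database the missing-origin pattern is detected exactly; between
#' databases only release-date intervals are comparable, so this operation is
#' a candidate generator, not a classifier. A sentence becomes a candidate
#' for having been copied from `source_group` into `target_group` and then
#' lost from its source when:
#' \enumerate{
#'   \item its first dated appearance in the source does not come after its
#'     first appearance in the target (no time travel in the claimed
#'     direction);
#'   \item it is absent from every source database's latest release (the
#'     origin lost it);
#'   \item it is present in some target release whose interval starts at or
#'     after the interval in which the source last carried it (the copy
#'     survived the loss).
#' }
#' `direction_confidence` is `"ordered"` when the source first-seen interval
#' ends no later than the target first-seen interval starts, and
#' `"ambiguous"` when the two intervals overlap — release granularity then
#' cannot order the appearances.
#'
#' @param indexes An `occurrence_index` or a list of them.
#' @param source_group,target_group Group labels to test (must differ).
#' @param grouping Named character vector database -> group; defaults to the
#'   groupings stored in the indexes.
#' @return Tibble with one row per candidate sentence: `sentence`,
#'   `source_group`, `target_group`, `source_first_start`,
#'   `source_first_end`, `source_last_start`, `source_last_end`,
#'   `target_first_start`, `target_first_end`, `target_still_present`,
#'   `direction_confidence`.
#' @export
cross_missing_origin <- function(indexes, source_group, target_group,
                                 grouping = NULL) {
  indexes <- as_index_list(indexes)
  grouping <- combined_grouping(indexes, grouping)
  if (identical(source_group, target_group)) {
    abort("`source_group` and `target_group` must differ.")
  }
  for (g in c(source_group, target_group)) {
    if (!g %in% grouping) abort(paste0("Unknown group: '", g, "'."))
  }
  tl <- bind_rows(lapply(indexes, function(ix) ix$timelines))
  iv <- date_intervals(tl)
  occ <- bind_rows(lapply(indexes, function(ix) {
    distinct(ix$occurrences, .data$database, .data$release, .data$ordinal,
             .data$sentence)
  })) %>%
    left_join(iv, by = c("database", "release", "ordinal")) %>%
    mutate(group = unname(grouping[.data$database]))
  latest <- tl %>%
    group_by(.data$database) %>%
    summarise(latest_ordinal = max(.data$ordinal), .groups = "drop")
  occ <- left_join(occ, latest, by = "database")

  src <- filter(occ, .data$group == !!source_group)
  tgt <- filter(occ, .data$group == !!target_group)
  shared <- intersect(unique(src$sentence), unique(tgt$sentence))
  empty <- tibble(sentence = character(), source_group = character(),
                  target_group = character(),
                  source_first_start = as.Date(character()),
                  source_first_end = as.Date(character()),
                  source_last_start = as.Date(character()),
                  source_last_end = as.Date(character()),
                  target_first_start = as.Date(character()),
                  target_first_end = as.Date(character()),
                  target_still_present = logical(),
                  direction_confidence = character())
  if (!length(shared)) return(empty)

  out <- list()
  for (s in sort(shared)) {
    ss <- src[src$sentence == s, ]
    ts <- tgt[tgt$sentence == s, ]
    # lost from the source: absent from every source database's latest release
    if (any(ss$ordinal == ss$latest_ordinal)) next
    sf <- ss[order(ss$start, ss$database, ss$ordinal), ][1, ]
    sl <- ss[order(ss$start, ss$database, ss$ordinal,
                   decreasing = TRUE), ][1, ]
    tf <- ts[order(ts$start, ts$database, ts$ordinal), ][1, ]
    # claimed direction must not run backwards in time
    if (sf$start > tf$start) next
    tf_end <- if (is.na(tf$end)) structure(Inf, class = "Date") else tf$end
    if (tf_end <= sf$start) next
    # the copy must survive into (or past) the interval of the source loss
    if (!any(ts$start >= sl$start)) next
    sf_end <- if (is.na(sf$end)) structure(Inf, class = "Date") else sf$end
    conf <- if (sf_end <= tf$start) "ordered" else "ambiguous"
    out[[length(out) + 1L]] <- tibble(
      sentence = s, source_group = source_group, target_group = target_group,
      source_first_start = sf$start, source_first_end = sf$end,
      source_last_start = sl$start, source_last_end = sl$end,
      target_first_start = tf$start, target_first_end = tf$end,
      target_still_present = any(ts$ordinal == ts$latest_ordinal),
      direction_confidence = conf)
  }
  if (!length(out)) return(empty)
  bind_rows(out)
}

#' Write the shared-sentence partition and candidate reports
#'
#' The partition goes to TSV (`combination`, `n_groups`, `count`);
#' cross-database candidates, if supplied, to JSON lines, one object per
#' candidate with ISO dates.
#'
#' @param partition Output of [shared_partition()].
#' @param path Output TSV path.
#' @param candidates Optional output of [cross_missing_origin()].
#' @param candidates_path Output JSON-lines path (required with
#'   `candidates`).
#' @return `partition`, invisibly.
#' @export
write_crossdb_report <- function(partition, path, candidates = NULL,
                                 candidates_path = NULL) {
  readr::write_tsv(partition, path)
  if (!is.null(candidates)) {
    if (is.null(candidates_path)) {
      abort("`candidates_path` is required when writing candidates.")
    }
    con <- file(candidates_path, open = "wb")
    on.exit(close(con))
    for (i in seq_len(nrow(candidates))) {
      row <- as.list(candidates[i, ])
      row <- lapply(row, function(v) {
        if (inherits(v, "Date")) format(v, "%Y-%m-%d") else v
      })
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, null = "null",
                                  na = "null"),
                 con, useBytes = TRUE)
    }
  }
  invisible(partition)
}
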