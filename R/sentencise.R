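#' Normalize a raw sentence into its canonical key
#'
#' Sentence identity throughout the package is exact string equality of the
#' normalized form: the raw sentence lower-cased, with every run of whitespace
#' (spaces, tabs, newlines) collapsed to a single space and outer whitespace
#' trimmed. Nothing else is changed — no stemming, no stop-word removal, no
#' punctuation edits — so a match between two normalized sentences is verbatim
#' reuse up to case and layout.
#'
#' Lower-casing is the simple per-character mapping of [tolower()], not
#' aggressive Unicode case folding, so results are locale-independent and the
#' operation is idempotent.
#'
#' @param raw Character vector of raw sentences. Each element must contain at
#'   least one non-whitespace character.
#' @return Character vector of normalized sentence keys, same length as `raw`.
#' @examples
#' normalize_sentence("May be a transcription factor with\nimportant functions.")
#' @export
normalize_sentence <- function(raw) {
  if (!is.character(raw)) abort("`raw` must be a character vector.")
  if (length(raw) && any(is.na(raw) | !nzchar(trimws(raw)))) {
    abort("normalize_sentence(): input must contain a non-whitespace character.")
  }
  x <- gsub("[ \t\r\n\f\v]+", " ", raw)
  trimws(tolower(x))
}

#' Default abbreviation list for the sentence splitter
#'
#' Tokens (compared lower-case, final dot removed) after which a period is not
#' treated as a sentence terminator. Biological annotation is dense in dotted
#' abbreviations — species initials ("E. coli"), "et al.", "approx." — and a
#' splitter unaware of them fragments sentences and inflates every count.
#'
#' @return Character vector of abbreviation tokens.
#' @export
reuse_abbreviations <- function() {
  c("e", "g", "i", "sp", "spp", "subsp", "approx", "al", "et", "cf",
    "fig", "figs", "ca", "vs", "st", "no", "var", "syn", "strain")
}

#' Split plain annotation text into raw sentences
#'
#' Splits after `.`, `!` or `?` when the terminator is followed by whitespace
#' and a letter or digit, unless (for `.`) the token immediately before the
#' terminator is in the abbreviation list. Blank lines are hard boundaries:
#' adjacent annotation topics are stored separated by a blank line so that a
#' topic lacking terminal punctuation can never fuse with the next one.
#'
#' The splitter removes only inter-sentence whitespace: concatenating the
#' result with single spaces and re-collapsing whitespace reproduces the
#' whitespace-normalized input. Terminator punctuation stays attached to its
#' sentence. The splitting rule is a package choice (any published sentence
#' count is sensitive to it) and is pluggable via the `splitter` argument of
#' [extract_sentences()].
#'
#' @param text A single character string of plain text (markup already
#'   stripped).
#' @param abbreviations Character vector of tokens blocking a split at a
#'   following period; defaults to [reuse_abbreviations()].
#' @return Character vector of raw sentence strings, in order; `character(0)`
#'   for empty or all-whitespace text.
#' @examples
#' split_sentences("Binds DNA. Required for vision.")
#' split_sentences("Found in E. coli strains.")
#' @export
split_sentences <- function(text, abbreviations = reuse_abbreviations()) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    abort("`text` must be a single string.")
  }
  if (!nzchar(trimws(text))) return(character(0))
  paras <- strsplit(text, "\n[ \t]*\n+")[[1]]
  out <- unlist(lapply(paras, split_one, abbreviations = abbreviations),
                use.names = FALSE)
  out[nzchar(trimws(out))]
}

# Split a single paragraph (no blank lines) at sentence terminators.
split_one <- function(para, abbreviations) {
  m <- gregexpr("[.!?](?=[ \t\r\n]+[A-Za-z0-9])", para, perl = TRUE)[[1]]
  cuts <- integer(0)
  if (m[1] != -1L) {
    for (pos in as.integer(m)) {
      term <- substr(para, pos, pos)
      if (term == ".") {
        before <- substr(para, 1L, pos - 1L)
        word <- regmatches(before, regexpr("[A-Za-z0-9]+$", before))
        if (length(word) && tolower(word) %in% abbreviations) next
      }
      cuts <- c(cuts, pos)
    }
  }
  if (!length(cuts)) return(trimws(para))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, nchar(para))
  trimws(substring(para, starts, ends))
}

#' Extract normalized sentences from annotation text
#'
#' Composition of [split_sentences()] and [normalize_sentence()]: the ordered
#' sequence of normalized sentence keys of a text. Duplicate sentences within
#' one text are preserved (multiset semantics) — within-entry repetition is
#' real redundancy and counts toward the total measure.
#'
#' @param text A single character string of plain annotation text.
#' @param splitter Function `(text) -> character` producing raw sentence
#'   strings; defaults to [split_sentences()]. Swap in another segmenter to
#'   change the splitting rule globally; all counts depend on it.
#' @param min_chars Minimum number of characters a normalized sentence must
#'   have to be kept; `0` (the default) keeps everything — no length filter is
#'   applied unless requested.
#' @return Character vector of normalized sentence keys, possibly with
#'   duplicates, in text order.
#' @examples
#' extract_sentences("May be a transcription factor. Binds DNA.")
#' @export
extract_sentences <- function(text, splitter = split_sentences, min_chars = 0L) {
  raw <- splitter(text)
  raw <- raw[nzchar(trimws(raw))]
  if (!length(raw)) return(character(0))
  keys <- normalize_sentence(raw)
  keys[nchar(keys) >= min_chars]
}
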