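# Fixture builders and independent brute-force oracles used across the suite.
# Oracles are direct transcriptions of the pattern definitions over a logical
# presence matrix; they never touch the package's run/index machinery.

# corpus in which one database D carries one probe sentence per presence
# matrix: sentence k is present in entry e at release r iff bit (e-1)*R + r
# of k is set. Covers every binary matrix of the given shape in one corpus.
index_from_all_matrices <- function(n_entries = 3L, n_releases = 4L,
                                    db = "D") {
  codes <- seq_len(2L^(n_entries * n_releases) - 1L)
  sentences <- sprintf("matrix %04d pattern probe.", codes)
  texts <- matrix("", n_entries, n_releases)
  for (e in seq_len(n_entries)) {
    for (r in seq_len(n_releases)) {
      bit <- (e - 1L) * n_releases + r
      here <- bitwAnd(codes, bitwShiftL(1L, bit - 1L)) != 0L
      texts[e, r] <- paste(sentences[here], collapse = " ")
    }
  }
  entries <- tibble::tibble(
    database = db,
    release = rep(sprintf("r%d", seq_len(n_releases)), each = n_entries),
    entry = rep(sprintf("E%d", seq_len(n_entries)), times = n_releases),
    text = as.vector(texts))
  timelines <- tibble::tibble(
    database = db, release = sprintf("r%d", seq_len(n_releases)),
    date = as.Date("2000-01-01") + 365 * (seq_len(n_releases) - 1L))
  list(index = build_index(versioned_corpus(entries, timelines)),
       codes = codes, sentences = sentences,
       n_entries = n_entries, n_releases = n_releases)
}

presence_from_code <- function(code, n_entries, n_releases) {
  pres <- matrix(FALSE, n_entries, n_releases)
  for (e in seq_len(n_entries)) {
    for (r in seq_len(n_releases)) {
      bit <- (e - 1L) * n_releases + r
      pres[e, r] <- bitwAnd(code, bitwShiftL(1L, bit - 1L)) != 0L
    }
  }
  pres
}

# brute-force pattern labels of one sentence from its presence matrix
oracle_labels <- function(pres) {
  R <- ncol(pres)
  transient <- FALSE
  possibly <- FALSE
  for (e in seq_len(nrow(pres))) {
    runs <- rle(pres[e, ])
    ends <- cumsum(runs$lengths)
    for (i in seq_along(runs$values)) {
      if (runs$values[i] && runs$lengths[i] == 1L) {
        if (ends[i] == R) possibly <- TRUE else transient <- TRUE
      }
    }
  }
  missing_origin <- FALSE
  if (any(pres)) {
    f <- min(which(apply(pres, 2, any)))
    origin <- which(pres[, f])
    firsts <- apply(pres, 1, function(x) if (any(x)) min(which(x)) else Inf)
    secondaries <- which(firsts > f & is.finite(firsts))
    if (f < R) {
      for (m in (f + 1L):R) {
        if (!any(pres[origin, m]) && any(pres[origin, m - 1L]) &&
            length(secondaries) && any(pres[secondaries, m])) {
          missing_origin <- TRUE
          break
        }
      }
    }
  }
  c(transient = transient,
    possibly_transient = possibly && !transient,
    missing_origin = missing_origin)
}

# brute-force maximal presence runs of one entry row (independent of the
# package's vectorized run computation)
oracle_runs <- function(row) {
  runs <- rle(row)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values
  data.frame(start_idx = starts[keep], end_idx = ends[keep],
             censored = ends[keep] == length(row))
}

# a small corpus from an explicit presence map of one sentence plus optional
# filler text per entry
corpus_one_sentence <- function(presence, sentence = "probe sentence one.",
                                db = "D", dates = NULL) {
  n_entries <- nrow(presence)
  n_releases <- ncol(presence)
  if (is.null(dates)) {
    dates <- as.Date("2000-06-15") + 365 * (seq_len(n_releases) - 1L)
  }
  entries <- tibble::tibble(
    database = db,
    release = rep(sprintf("r%d", seq_len(n_releases)), each = n_entries),
    entry = rep(rownames(presence) %||% sprintf("E%d", seq_len(n_entries)),
                times = n_releases),
    text = as.vector(ifelse(presence, sentence, "")))
  timelines <- tibble::tibble(
    database = db, release = sprintf("r%d", seq_len(n_releases)),
    date = dates)
  versioned_corpus(entries, timelines)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# the printed UniProtKB CC block, as it appears in a DAT file
uniprot_cc_fixture <- function() {
  c("ID   TEST1_HUMAN             Reviewed;         352 AA.",
    "AC   P47902; Q8TBW5;",
    "DT   01-NOV-1995, integrated into UniProtKB/Swiss-Prot.",
    "DE   RecName: Full=Homeobox protein SIX3;",
    "CC   -!- FUNCTION: May be a transcription factor with important functions",
    "CC       in eye and nasal development.",
    "SQ   SEQUENCE   352 AA;  38935 MW;  52E70AF5478C4AB5 CRC64;",
    "//")
}

# InterPro timeline reconstruction: sentence debuts in one entry in 2001,
# propagates to a second in 2002, leaves the origin in 2003 while the
# secondary keeps it for another release.
fig2_corpus <- function() {
  s <- paste0("Pyelonephritogenic E.coli specifically invade the ",
              "uroepithelium by expressing between 100 and 300 pili on ",
              "their cell surface.")
  pres <- rbind(IPR004086 = c(TRUE, TRUE, FALSE, FALSE),
                IPR005430 = c(FALSE, TRUE, TRUE, FALSE))
  corpus_one_sentence(pres, sentence = s, db = "InterPro",
                      dates = as.Date(paste0(2001:2004, "-01-01")))
}

# two-database reconstruction: the sentence appears first in the source
# database, percolates to the target, then disappears from the source while
# persisting in the target — invisible to either database alone.
fig3_corpora <- function() {
  s <- "this motif is found in several bacterial adhesion proteins."
  src_pres <- rbind(PR00001 = c(rep(TRUE, 6), rep(FALSE, 5)))
  src <- corpus_one_sentence(src_pres, sentence = s, db = "PRINTS",
                             dates = as.Date(paste0(1999:2009, "-03-01")))
  tgt_pres <- rbind(IRP001055 = rep(TRUE, 10),
                    IPR018298 = c(rep(FALSE, 8), TRUE, TRUE))
  tgt <- corpus_one_sentence(tgt_pres, sentence = s, db = "InterPro",
                             dates = as.Date(paste0(2000:2009, "-06-01")))
  list(source = src, target = tgt)
}
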