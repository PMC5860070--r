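---
title: "Measuring sentence reuse and provenance patterns in versioned annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sentence reuse and provenance patterns in versioned annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annoreuse)
```

## The model

annoreuse treats the free-text annotation of a versioned database as a set
of sentences and a sentence as the unit of provenance. The working
assumption is that annotation text is copied largely verbatim — between
entries of one database and between databases — so an identical sentence in
two places very likely shares a history. The method is deliberately blunt:
sentences are compared by exact string equality after lower-casing and
whitespace normalization, with no stemming, stop-word removal or fuzzy
matching. This trades recall for precision: a match found this way is
almost certainly a real copy, while any edit to a copy silently breaks the
trail (a limitation the package demonstrates rather than hides; see the
last section).

The data model has three layers.

1. **Versioned corpus.** Per database, an ordered, dated release timeline;
   per entry per release, one plain-text annotation block. Within a
   database, time is the release *ordinal* (timeline position), because
   release dates may tie; dates matter only for cross-database work, where
   a record's date is the date of the release carrying it — an upper bound
   on when its content appeared, with slack equal to the release period.
   An entry absent from a release has simply no record: absence is removal,
   there are no tombstones, and deletion of an entry terminates the runs of
   all its sentences.

2. **Occurrence index.** Every entry text is split into sentences and
   normalized; each occurrence links (database, entry, release, sentence)
   with a slot count. Within-entry duplicates count toward the *total* and
   multiplicity measures (they are real redundancy mass), but presence over
   time is binary per release: presence runs model entry membership, totals
   model redundancy. This distinction is deliberate and isolated behind the
   multiplicity map, since one could equally argue for counting
   within-entry duplicates once; the package documents its choice rather
   than hiding it.

3. **Presence runs.** For each (sentence, entry), the maximal contiguous
   ordinal intervals of presence. A run touching the database's latest
   release is *censored*: its future is unobservable, which is exactly the
   transient / possibly-transient distinction.

## Sentence extraction

Normalization (`normalize_sentence()`) lower-cases with the simple
per-character mapping (locale-independent, idempotent) and collapses every
whitespace run to a single space. Nothing else changes.

Sentence *splitting* is underdetermined by the method's description, and
every count downstream is sensitive to it, so the rule is explicit and
pluggable. The default splits after `.`, `!` or `?` followed by whitespace
and a letter or digit, except when the token before a period is in a
curated abbreviation list (`reuse_abbreviations()`: species initials,
`et al`, `approx.`, `fig.` and similar — biological text is dense in dotted
abbreviations, and a canonical missing-origin example sentence itself
contains an organism initial). Splitting runs before lower-casing because
capitalization is a splitting cue. Blank lines are hard boundaries: the DAT
adapter joins comment topics with a blank-line separator precisely so that
a topic lacking terminal punctuation can never fuse with the next topic —
topics are independent statements. No minimum-length filter is applied by
default; an optional `min_chars` threshold exists but is off. Users with a
different segmenter can pass any `splitter` function to
`extract_sentences()` / `build_index()`; all counts then follow it.

## Pattern detectors

All three detectors count at sentence level: one label per sentence per
database, because a sentence needs to exhibit a pattern in only a single
entry, witnessed by its earliest qualifying run (ties broken by entry id
for determinism).

- **Transient**: some run has length 1 and is not censored. Requires at
  least 2 releases; in a single-release database transience is
  unobservable and the detector refuses rather than returning a vacuous
  answer.
- **Possibly transient**: some censored run has length 1 — new in the
  latest release. A sentence that is also transient elsewhere is counted
  as transient only (precedence), treating possibly-transient as the
  unclassifiable remainder rather than a pattern of its own. An
  alternative reading — "singleton in the latest version" — exists; the
  new-in-latest-release reading is adopted because it is the censored
  complement of transience, which is what the remainder is for.
- **Missing origin**: with `f` the debut ordinal and `O` the debut entry
  set, the label fires at the first `m > f` where no entry of `O` carries
  the sentence, some entry of `O` carried it at `m − 1`, and some entry
  outside `O` whose own debut is strictly after `f` carries it at `m`.
  Design points: simultaneous debuts share origin status (at release
  granularity no single origin is distinguishable), so *all* of `O` must
  have dropped the sentence; entries debuting at `f` are origin members,
  never secondaries; only the first qualifying removal is witnessed, and
  later re-introductions do not retract the label. The degenerate case
  where a secondary debuts exactly at the removal release is counted —
  propagation and removal observed at the same release still satisfy the
  definition. Detection requires at least 3 releases (debut, propagation,
  removal need three observation points).

These definitions are verified two independent ways: exhaustively, against
a brute-force transcription of the definitions over every binary presence
matrix of 3 entries × 4 releases (4,095 non-empty matrices, all embedded as
probe sentences in a single corpus); and by recovery of planted instances
in synthetic corpora (below).

## Cross-database analysis

Sharing between databases is reported as a combination partition: every
sentence that ever occurred anywhere is assigned to the exact set of
database *groups* in which it ever occurred. Lifetime (any release) rather
than latest-release occurrence is used because cross-database flows span
years and a shared sentence may already be gone from current releases.
Grouping (e.g. collapsing Swiss-Prot and TrEMBL into UniProtKB) is a
configurable database-to-label map; lifetime unique counts are otherwise
strictly per database, and deduplication happens on the sentence key across
the union.

Cross-database missing-origin detection cannot reuse the within-database
machinery: release ordinals of different databases are incomparable, and
date intervals overlap. The package therefore ships a *candidate
generator*, not a classifier. A sentence is a candidate for
source-to-target copying with subsequent source loss when its first dated
appearance in the source does not come after its first appearance in the
target, it is absent from every source database's latest release, and it
persists in some target release whose interval starts at or after the
interval of the source's last possession. When the two first-seen intervals
overlap rather than strictly order, the candidate is flagged `ambiguous`
instead of being forced into a verdict — at release granularity the copy
direction is genuinely unknowable from the data.

## The synthetic generator

`generate_corpus()` emulates the relevant mechanics of a multi-database
ecosystem: a fixed entry population per database; a shared sentence
vocabulary, so reuse exists from the first release; per-release background
processes — sentence birth, intra-database copying with a one-release lag
(the smallest observable propagation), removal, and token-substitution
edits; and planted pattern instances written on top at exactly the releases
their definitions require. Planted sentences carry a reserved token
(`xxplanted`) that the background vocabulary never produces, so recovery
metrics are exact rather than probabilistic. Generation is a pure function
of the config including its seed, and `verify_ground_truth()` re-checks
every planted tuple against the emitted text — presence on the planted
span, absence at the flanking releases the pattern requires.

Default calendars are regular, with sibling databases offset by half a
release period so cross-database planted candidates order strictly
(`ordered`); `cross_overlap = TRUE` aligns the calendars to exercise the
`ambiguous` flag, and `cross_edit = TRUE` edits the target copies to
demonstrate the exact-matching limitation.

What the generator does **not** emulate: natural language (sentences are
token strings), realistic sentence-length or reuse-size distributions, the
heavy skew of real databases (where one sentence can fill millions of
slots), entry creation and deletion over time, and inter-database
background copying (cross-database content arises only from planting).
Passing tests therefore show that the measures and detectors implement
their definitions exactly and recover planted signals perfectly against a
controlled background; they do not show anything about pattern *rates* in
real databases, which depend on real dynamics and on the sentence splitter.

## Numerical and interface choices

- Release ordinals are 1-based timeline positions; dates never order
  releases within a database.
- Percentages are kept at full precision; rounding is presentational.
- Rankings (`top_reused()`) and all written reports are deterministically
  sorted (count descending, then lexicographic key), so outputs are
  byte-stable and diffable; two writes of the same corpus are identical.
- The canonical corpus format is flat, line-delimited text (with a
  JSON-lines dialect) rather than a relational store: diff-friendly,
  dependency-free, order-insensitive on read. The occurrence index
  likewise persists to a flat text file; the storage contract is only that
  queries be exact and deterministic.
- Degenerate inputs are defined, not accidental: empty text yields no
  sentences, an empty release reports zero counts (percentages are an
  error there, not `NaN`), an unseen sentence yields an empty support set
  and a zero-row timeline matrix.
- All-whitespace input to `normalize_sentence()` is a caller error — the
  splitter never emits such fragments.

## Validation scale

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in minutes while still exercising every code
path: exhaustive detector-oracle comparison at 3 entries × 4 releases;
planted-pattern recovery in a 2-database, 12-release, 200-entry ecosystem
with 50 + 50 + 50 + 10 planted instances; conservation invariants over 100
random corpora of at most 5 releases × 10 entries; 1,000-case
normalization properties. Reproducing published reuse measurements for real
databases would require their full historical release archives and is out
of scope; the corpus format and the DAT adapter are the intended entry
points for anyone holding such archives.

## Known limitations

- Exact matching misses every edited copy; the `cross_edit` demonstration
  quantifies this as zero recall on edited plants.
- Any sentence-count statistic depends on the segmentation rule; compare
  counts only across runs with the same splitter.
- Release-date granularity bounds all cross-database timing claims; the
  candidate generator surfaces ambiguity rather than resolving it.
- Within-entry duplicate handling (counted in totals, binary in runs) is a
  documented convention, not the only defensible one.
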