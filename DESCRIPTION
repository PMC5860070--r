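Package: annoreuse
Title: Sentence Reuse and Provenance Patterns in Versioned Database Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying verbatim sentence reuse in the free-text
    annotation of versioned biological databases and for mining the
    propagation patterns that reuse leaves behind. Annotation text is split
    into normalized sentences that act as informal provenance markers; an
    occurrence index links each sentence to the entries and releases that
    carry it. On top of the index the package computes per-release reuse
    measures (total, unique and singleton sentence counts), detects the
    transient, possibly-transient and missing-origin propagation patterns
    within a database, partitions sentences shared between databases, and
    searches for cross-database missing-origin candidates using release-date
    intervals. A synthetic corpus generator with planted pattern instances
    and machine-checkable ground truth supports validation end to end, and a
    command-line interface ties ingestion, analysis and reporting together.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
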