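Package: intronaut
Title: Splice-Junction Quality Control, Mis-Splicing Ratios and Intron
    Database Construction from RNA-Seq Split Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a hierarchical relational database of annotated introns
    and the novel splice junctions derived from them, starting from
    split-read junction tables produced by short-read RNA-seq aligners.
    Provides an intron catalogue extractor for Ensembl-style GTF
    annotation, three junction quality-control filters (implied intron
    length, contig whitelist, blacklist-region overlap), a seven-way
    junction classifier (annotated, novel donor, novel acceptor, novel
    combo, novel exon skip, ambiguous, unannotated), an evidence-based
    pairing of each novel donor/acceptor junction to a unique parent
    intron, per-tissue mis-splicing ratios (MSR_D, MSR_A) with support
    statistics, splice-site sequence windows and score-track summaries,
    and an SQLite exporter with query helpers. A fully self-contained
    synthetic-data generator with a ground-truth manifest makes every
    pipeline stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    generics,
    ggplot2,
    DBI,
    RSQLite,
    rtracklayer,
    GenomicRanges,
    IRanges,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
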