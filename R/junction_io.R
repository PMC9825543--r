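#' Read the sample metadata table
#'
#' The metadata TSV must have columns `sample_id`, `tissue` and `excluded`.
#' Samples flagged `excluded = TRUE` (for example, those failing a study's
#' upstream quality-control criteria) are dropped from every downstream
#' stage; all per-tissue statistics are computed over the remaining samples.
#'
#' @param path Path to the TSV file.
#' @return Tibble with `sample_id`, `tissue`, `excluded`.
#' @export
read_sample_metadata <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  assert_columns(raw, c("sample_id", "tissue", "excluded"), "sample metadata")
  dup <- raw$sample_id[duplicated(raw$sample_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate sample_id in metadata: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  excl <- parse_boolean(raw$excluded)
  if (anyNA(excl)) {
    abort(sprintf("unknown boolean token in 'excluded': %s",
                  paste(unique(raw$excluded[is.na(excl)]), collapse = ", ")))
  }
  out <- tibble(sample_id = raw$sample_id, tissue = raw$tissue,
                excluded = excl)
  if (nrow(out) == 0) warn("sample metadata contains no samples")
  if (any(!out$excluded & (is.na(out$tissue) | out$tissue == ""))) {
    abort("non-excluded samples must have a non-empty tissue")
  }
  out
}

parse_boolean <- function(x) {
  dplyr::case_when(
    tolower(x) %in% c("true", "t", "1", "yes") ~ TRUE,
    tolower(x) %in% c("false", "f", "0", "no") ~ FALSE,
    TRUE ~ NA)
}

#' Read per-sample split-read junction tables
#'
#' Reads junction evidence in one of three dialects and merges records with
#' identical `(chrom, strand, start, end)` across samples into one junction
#' with a sparse per-sample count table. All coordinates are normalised to
#' the 1-based inclusive implied-intron span.
#'
#' * `star_sj` — one STAR `SJ.out.tab` per sample (9 columns; strand code
#'   0 = unknown, 1 = `+`, 2 = `-`; count taken from the uniquely-mapped
#'   read column). `sample_ids` gives the sample of each file.
#' * `bed` — one BED6 file per sample (0-based half-open; the score field is
#'   the read count).
#' * `tsv_matrix` — a single junction-coordinates TSV (`chrom`, `start`,
#'   `end`, `strand`) in `paths[1]` plus a triplet counts file `counts_path`
#'   with columns `junction` (1-based row index into the coordinate file),
#'   `sample_id`, `count`.
#'
#' Zero or negative counts are dropped (a zero count means "not observed"
#' and is never stored); a line whose start exceeds its end is an error, as
#' is the same sample id appearing twice (counts are never silently summed).
#'
#' @param paths Character vector of input files.
#' @param dialect One of `"star_sj"`, `"bed"`, `"tsv_matrix"`.
#' @param sample_ids For the per-sample dialects, a character vector parallel
#'   to `paths`.
#' @param counts_path Counts triplet file for `dialect = "tsv_matrix"`.
#' @return A list with tibbles `junctions` (`junction_id`, `chrom`, `strand`,
#'   `start`, `end`, `implied_length`) and `counts`
#'   (`junction_id`, `sample_id`, `count`).
#' @export
read_junctions <- function(paths, dialect = c("star_sj", "bed", "tsv_matrix"),
                           sample_ids = NULL, counts_path = NULL) {
  dialect <- match.arg(dialect)
  if (dialect %in% c("star_sj", "bed")) {
    if (is.null(sample_ids) || length(sample_ids) != length(paths)) {
      abort("sample_ids must be given, one per input file")
    }
    if (anyDuplicated(sample_ids)) {
      abort(sprintf("duplicate sample id(s) in manifest: %s",
                    paste(unique(sample_ids[duplicated(sample_ids)]),
                          collapse = ", ")))
    }
    per <- purrr::map2(paths, sample_ids, function(p, s) {
      tab <- switch(dialect,
                    star_sj = read_star_sj(p),
                    bed = read_bed_junctions(p))
      tab$sample_id <- s
      tab
    })
    long <- bind_rows(per)
  } else {
    if (is.null(counts_path)) abort("tsv_matrix dialect needs counts_path")
    coords <- readr::read_tsv(paths[1], col_types = readr::cols(
      chrom = "c", start = "i", end = "i", strand = "c"))
    trip <- readr::read_tsv(counts_path, col_types = readr::cols(
      junction = "i", sample_id = "c", count = "d"))
    if (any(trip$junction < 1 | trip$junction > nrow(coords))) {
      abort("counts triplet references a junction row outside the coordinate file")
    }
    long <- coords[trip$junction, ] %>%
      mutate(count = trip$count, sample_id = trip$sample_id)
  }
  if (any(long$start > long$end)) {
    abort("junction with start > end in input")
  }
  long <- filter(long, .data$count > 0)
  long <- mutate(long,
                 junction_id = junction_coord_id(.data$chrom, .data$start,
                                                 .data$end, .data$strand))
  dup <- long %>% count(.data$junction_id, .data$sample_id) %>% filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("junction %s listed more than once for sample %s",
                  dup$junction_id[1], dup$sample_id[1]))
  }
  junctions <- long %>%
    distinct(.data$junction_id, .data$chrom, .data$strand,
             .data$start, .data$end) %>%
    mutate(implied_length = .data$end - .data$start + 1L) %>%
    arrange(.data$chrom, .data$start, .data$end, .data$strand)
  counts <- long %>%
    transmute(junction_id = .data$junction_id, sample_id = .data$sample_id,
              count = as.integer(.data$count)) %>%
    arrange(.data$junction_id, .data$sample_id)
  list(junctions = junctions, counts = counts)
}

read_star_sj <- function(path) {
  tab <- readr::read_tsv(path, col_names = c(
    "chrom", "start", "end", "strand_code", "motif", "annotated",
    "n_unique", "n_multi", "overhang"),
    col_types = "ciiiiiiii")
  tab %>%
    transmute(chrom = .data$chrom, start = .data$start, end = .data$end,
              strand = dplyr::case_when(.data$strand_code == 1L ~ "+",
                                        .data$strand_code == 2L ~ "-",
                                        TRUE ~ "*"),
              count = .data$n_unique)
}

read_bed_junctions <- function(path) {
  tab <- readr::read_tsv(path, col_names = c(
    "chrom", "start0", "end0", "name", "score", "strand"),
    col_types = "ciicdc")
  tab %>%
    transmute(chrom = .data$chrom, start = .data$start0 + 1L,
              end = .data$end0,
              strand = if_else(.data$strand %in% c("+", "-"), .data$strand, "*"),
              count = .data$score)
}

#' Read a blacklist BED file
#'
#' Regions are converted from BED's 0-based half-open convention to the
#' package-wide 1-based inclusive intervals.
#'
#' @param path BED file (first three columns used).
#' @return Tibble with `chrom`, `start`, `end`.
#' @export
read_blacklist_bed <- function(path) {
  tab <- readr::read_tsv(path, col_names = FALSE,
                         col_types = readr::cols(.default = "c"))
  out <- tibble(chrom = tab[[1]],
                start = as.integer(tab[[2]]) + 1L,
                end = as.integer(tab[[3]]))
  if (any(out$start > out$end)) abort("invalid blacklist interval (start > end)")
  out
}

removed_of <- function(kept, input) {
  attr(kept, "removed_count") <- nrow(input) - nrow(kept)
  attr(kept, "removed_ids") <- setdiff(input$junction_id, kept$junction_id)
  kept
}

#' Number of junctions removed by the last applied filter
#'
#' @param junctions A tibble returned by one of the QC filters.
#' @return Integer count.
#' @export
removed_count <- function(junctions) {
  attr(junctions, "removed_count") %||% 0L
}

#' Junction QC filter: minimum implied intron length
#'
#' Removes junctions whose implied intron is shorter than `min_length` base
#' pairs (default 25 bp, the minimum span that can hold all essential
#' splicing signals); a junction of exactly `min_length` is kept.
#'
#' @param junctions Junction tibble (needs `implied_length`).
#' @param min_length Minimum length in bp; must be >= 1.
#' @return The kept junctions, with attribute `removed_count`
#'   (see [removed_count()]).
#' @export
filter_min_length <- function(junctions, min_length = 25) {
  if (!is.numeric(min_length) || min_length < 1) {
    abort("min_length must be >= 1")
  }
  removed_of(filter(junctions, .data$implied_length >= min_length), junctions)
}

#' Junction QC filter: contig whitelist
#'
#' Removes junctions on contigs outside the whitelist — by default the
#' primary assembled chromosomes (see [default_chromosomes()]), which
#' excludes unplaced/unlocalized scaffolds and the mitochondrial contig.
#'
#' @param junctions Junction tibble.
#' @param whitelist Character vector of allowed contig names.
#' @return The kept junctions, with attribute `removed_count`.
#' @export
filter_chromosomes <- function(junctions, whitelist = default_chromosomes()) {
  removed_of(filter(junctions, .data$chrom %in% whitelist), junctions)
}

#' Junction QC filter: blacklist-region overlap
#'
#' Removes junctions whose implied-intron span shares at least one base with
#' a blacklist interval on the same contig (`mode = "span"`), or whose two
#' boundary bases do (`mode = "ends"`). Closed intervals that merely abut do
#' not intersect.
#'
#' @param junctions Junction tibble.
#' @param blacklist Tibble of 1-based inclusive intervals (`chrom`, `start`,
#'   `end`), e.g. from [read_blacklist_bed()]; `NULL` or empty keeps all.
#' @param mode `"span"` (default) or `"ends"`.
#' @return The kept junctions, with attribute `removed_count`.
#' @export
filter_blacklist <- function(junctions, blacklist, mode = c("span", "ends")) {
  mode <- match.arg(mode)
  if (is.null(blacklist) || nrow(blacklist) == 0) {
    return(removed_of(junctions, junctions))
  }
  lvls <- union(unique(junctions$chrom), unique(blacklist$chrom))
  bl <- GenomicRanges::GRanges(factor(blacklist$chrom, levels = lvls),
                               IRanges::IRanges(blacklist$start, blacklist$end))
  gr <- function(chrom, s, e) {
    GenomicRanges::GRanges(factor(chrom, levels = lvls),
                           IRanges::IRanges(s, e))
  }
  if (mode == "span") {
    hit <- IRanges::overlapsAny(gr(junctions$chrom, junctions$start,
                                   junctions$end), bl)
  } else {
    hit <- IRanges::overlapsAny(gr(junctions$chrom, junctions$start,
                                   junctions$start), bl) |
      IRanges::overlapsAny(gr(junctions$chrom, junctions$end,
                              junctions$end), bl)
  }
  removed_of(junctions[!hit, , drop = FALSE], junctions)
}

#' Apply the three junction quality-control filters
#'
#' Applies, in order, the minimum implied-intron-length filter, the contig
#' whitelist and the blacklist-overlap filter. The filters commute — the
#' order only affects how removals are attributed in the audit.
#'
#' @param junctions Junction tibble from [read_junctions()].
#' @param min_length Minimum implied intron length (bp).
#' @param whitelist Contig whitelist.
#' @param blacklist Blacklist interval tibble or `NULL`.
#' @param blacklist_mode `"span"` or `"ends"` (see [filter_blacklist()]).
#' @return List with `junctions` (the kept tibble) and `audit`, a tibble of
#'   `step`, `n_removed`, `n_kept`.
#' @export
apply_junction_qc <- function(junctions, min_length = 25,
                              whitelist = default_chromosomes(),
                              blacklist = NULL,
                              blacklist_mode = c("span", "ends")) {
  blacklist_mode <- match.arg(blacklist_mode)
  s1 <- filter_min_length(junctions, min_length)
  s2 <- filter_chromosomes(s1, whitelist)
  s3 <- filter_blacklist(s2, blacklist, blacklist_mode)
  audit <- tibble(step = c("min_length", "chromosomes", "blacklist"),
                  n_removed = c(removed_count(s1), removed_count(s2),
                                removed_count(s3)),
                  n_kept = c(nrow(s1), nrow(s2), nrow(s3)))
  list(junctions = as_tibble(s3), audit = audit)
}
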