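#' Build the annotated intron catalogue from a GTF file
#'
#' Parses an Ensembl-dialect GTF into gene, transcript and exon tables and
#' derives the deduplicated catalogue of annotated introns. Each intron is
#' the gap between a pair of consecutive exons of a transcript, expressed in
#' 1-based inclusive coordinates as `[prev_exon_end + 1, next_exon_start - 1]`
#' (the same convention STAR uses for `SJ.out.tab` spans). Introns with
#' identical coordinates across transcripts of one gene are collapsed into a
#' single catalogue row that accumulates all parent transcripts; the same
#' coordinates under two different genes yield one row per gene.
#'
#' Donor and acceptor positions are strand-aware: on `+` the donor is the
#' first intronic base (`start`) and the acceptor the last (`end`); on `-`
#' they are mirrored.
#'
#' @param gtf_path Path to a GTF file (optionally gzip-compressed) with
#'   `gene`, `transcript` and `exon` features carrying `gene_id` and
#'   `transcript_id` attributes.
#' @param mane_table Optional data frame with columns `transcript_id` and
#'   `mane_select` (logical) used when the GTF lacks `tag "MANE_Select"`
#'   annotations. Ignored for transcripts already tagged in the GTF.
#' @param tsl_policy How to summarise the transcript support level (TSL) of
#'   an intron over its parent transcripts: `"best"` (numerically smallest,
#'   i.e. strongest support; the default) or `"worst"` (numerically largest).
#' @return An object of class `intron_catalogue`: a list with tibbles
#'   `genes`, `transcripts`, `exons` and `introns`.
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "intronaut")
#' cat <- build_intron_catalogue(gtf)
#' cat$introns
#' @export
build_intron_catalogue <- function(gtf_path, mane_table = NULL,
                                   tsl_policy = c("best", "worst")) {
  tsl_policy <- match.arg(tsl_policy)
  if (!file.exists(gtf_path)) abort(sprintf("GTF file not found: %s", gtf_path))
  validate_gtf_lines(gtf_path)

  gr <- rtracklayer::import(gtf_path, format = "gtf")
  df <- as_tibble(as.data.frame(gr)) %>%
    mutate(seqnames = as.character(.data$seqnames),
           strand = as.character(.data$strand))
  # Ensembl ships the biotype as gene_biotype; GENCODE as gene_type.
  if (!"gene_biotype" %in% names(df) && "gene_type" %in% names(df)) {
    df <- rename(df, gene_biotype = "gene_type")
  }
  if (!"transcript_biotype" %in% names(df) && "transcript_type" %in% names(df)) {
    df <- rename(df, transcript_biotype = "transcript_type")
  }
  for (col in c("gene_biotype", "transcript_biotype", "gene_name",
                "transcript_support_level", "tag")) {
    if (!col %in% names(df)) df[[col]] <- NA_character_
  }

  genes <- df %>%
    filter(.data$type == "gene") %>%
    transmute(gene_id = .data$gene_id,
              symbol = .data$gene_name,
              chrom = .data$seqnames,
              strand = .data$strand,
              start = as.integer(.data$start),
              end = as.integer(.data$end),
              biotype = .data$gene_biotype,
              gene_length = as.integer(.data$end - .data$start + 1L))

  mane_ids <- scan_mane_select(gtf_path)
  transcripts <- df %>%
    filter(.data$type == "transcript") %>%
    transmute(transcript_id = .data$transcript_id,
              gene_id = .data$gene_id,
              biotype = dplyr::coalesce(.data$transcript_biotype, .data$gene_biotype),
              tsl = parse_tsl(.data$transcript_support_level),
              is_mane_select = .data$transcript_id %in% mane_ids |
                (!is.na(.data$tag) & .data$tag == "MANE_Select"))
  if (!is.null(mane_table)) {
    assert_columns(mane_table, c("transcript_id", "mane_select"), "mane_table")
    transcripts <- transcripts %>%
      left_join(as_tibble(mane_table), by = "transcript_id") %>%
      mutate(is_mane_select = .data$is_mane_select |
               dplyr::coalesce(.data$mane_select, FALSE)) %>%
      select(-"mane_select")
  }
  if (nrow(genes) == 0 && nrow(transcripts) > 0) {
    # tolerate GTFs without explicit gene features
    genes <- df %>%
      filter(.data$type %in% c("transcript", "exon")) %>%
      group_by(gene_id = .data$gene_id) %>%
      summarise(symbol = first(.data$gene_name),
                chrom = first(.data$seqnames),
                strand = first(.data$strand),
                start = as.integer(min(.data$start)),
                end = as.integer(max(.data$end)),
                biotype = first(.data$gene_biotype),
                .groups = "drop") %>%
      mutate(gene_length = .data$end - .data$start + 1L)
  }
  genes <- genes %>%
    left_join(count(transcripts, .data$gene_id, name = "n_transcripts"),
              by = "gene_id") %>%
    mutate(n_transcripts = dplyr::coalesce(.data$n_transcripts, 0L))

  exons <- df %>%
    filter(.data$type == "exon") %>%
    transmute(transcript_id = .data$transcript_id,
              gene_id = .data$gene_id,
              chrom = .data$seqnames,
              strand = .data$strand,
              start = as.integer(.data$start),
              end = as.integer(.data$end)) %>%
    arrange(.data$transcript_id, .data$start, .data$end) %>%
    group_by(.data$transcript_id) %>%
    mutate(exon_rank = row_number(), n_exons = n()) %>%
    ungroup()

  introns <- derive_introns(exons)
  if (nrow(introns) > 0) {
    introns <- introns %>%
      left_join(reported_tsl(introns, transcripts, tsl_policy), by = "intron_id") %>%
      left_join(flag_mane(introns, transcripts), by = "intron_id") %>%
      left_join(pct_protein_coding(introns, transcripts), by = "intron_id") %>%
      mutate(u2_intron = FALSE, u12_intron = FALSE)
  } else {
    introns <- introns %>%
      mutate(tsl_reported = integer(), in_mane = logical(),
             pct_protein_coding_tx = numeric(),
             u2_intron = logical(), u12_intron = logical())
  }

  structure(list(genes = genes, transcripts = transcripts,
                 exons = exons, introns = introns),
            class = "intron_catalogue")
}

#' @export
print.intron_catalogue <- function(x, ...) {
  cat(sprintf(
    "<intron_catalogue> %d genes, %d transcripts, %d exons, %d introns\n",
    nrow(x$genes), nrow(x$transcripts), nrow(x$exons), nrow(x$introns)))
  invisible(x)
}

# Pre-scan for structurally broken GTF lines so errors carry a line number.
validate_gtf_lines <- function(gtf_path) {
  lines <- readr::read_lines(gtf_path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- stringr::str_count(lines[body], stringr::fixed("\t")) + 1L
  bad <- which(body)[nf < 9L]
  if (length(bad) > 0) {
    abort(sprintf("malformed GTF line %d: expected 9 tab-separated fields, found %d",
                  bad[1], nf[which(which(body) == bad[1])]))
  }
  invisible(TRUE)
}

# rtracklayer keeps only one value for repeated attribute keys, so the
# multi-valued `tag` attribute needs a direct scan for MANE_Select.
scan_mane_select <- function(gtf_path) {
  lines <- readr::read_lines(gtf_path)
  hits <- lines[stringr::str_detect(lines, stringr::fixed('tag "MANE_Select"'))]
  unique(stringr::str_match(hits, 'transcript_id "([^"]+)"')[, 2])
}

# "5 (assigned to previous version 10)" -> 5L; "NA"/absent -> NA
parse_tsl <- function(x) {
  out <- suppressWarnings(as.integer(stringr::str_match(x, "^\\s*([1-5])")[, 2]))
  out
}

derive_introns <- function(exons) {
  empty <- tibble(intron_id = character(), chrom = character(),
                  strand = character(), start = integer(), end = integer(),
                  donor_pos = integer(), acceptor_pos = integer(),
                  length = integer(), gene_id = character(),
                  transcript_ids = list(), n_transcripts = integer())
  if (nrow(exons) == 0) return(empty)
  per_tx <- exons %>%
    arrange(.data$transcript_id, .data$exon_rank) %>%
    group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) %>%
    dplyr::reframe(istart = .data$end[-n()] + 1L,
                   iend = .data$start[-1L] - 1L) %>%
    rename(start = "istart", end = "iend")
  if (nrow(per_tx) == 0) return(empty)
  bad <- per_tx$end < per_tx$start
  if (any(bad)) {
    warn(sprintf("skipping %d exon pair(s) with abutting or overlapping exons (no intronic gap)",
                 sum(bad)))
    per_tx <- per_tx[!bad, , drop = FALSE]
  }
  if (nrow(per_tx) == 0) return(empty)
  introns <- per_tx %>%
    group_by(.data$gene_id, .data$chrom, .data$strand, .data$start, .data$end) %>%
    summarise(transcript_ids = list(sort(unique(.data$transcript_id))),
              n_transcripts = length(unique(.data$transcript_id)),
              .groups = "drop") %>%
    mutate(intron_id = intron_coord_id(.data$chrom, .data$start, .data$end,
                                       .data$strand, .data$gene_id),
           donor_pos = if_else(.data$strand == "-", .data$end, .data$start),
           acceptor_pos = if_else(.data$strand == "-", .data$start, .data$end),
           length = .data$end - .data$start + 1L) %>%
    select("intron_id", "chrom", "strand", "start", "end", "donor_pos",
           "acceptor_pos", "length", "gene_id", "transcript_ids",
           "n_transcripts") %>%
    arrange(.data$chrom, .data$start, .data$end, .data$strand, .data$gene_id)
  cross <- introns %>%
    count(.data$chrom, .data$strand, .data$start, .data$end) %>%
    filter(n > 1)
  if (nrow(cross) > 0) {
    inform(sprintf("%d intron coordinate(s) shared across genes; kept once per gene",
                   nrow(cross)))
  }
  introns
}

#' Summarise the transcript support level of each intron
#'
#' Reports, per intron, the TSL over its parent transcripts. Under the
#' default `"best"` policy this is the numerically smallest TSL (TSL 1 is
#' the strongest evidence grade), `NA` only when every parent is tslNA.
#'
#' @param introns Intron tibble from [build_intron_catalogue()] (needs
#'   `intron_id` and the `transcript_ids` list-column).
#' @param transcripts Transcript tibble with `transcript_id` and `tsl`.
#' @param tsl_policy `"best"` (min) or `"worst"` (max).
#' @return Tibble with `intron_id`, `tsl_reported`.
#' @export
reported_tsl <- function(introns, transcripts, tsl_policy = c("best", "worst")) {
  tsl_policy <- match.arg(tsl_policy)
  agg <- if (tsl_policy == "best") min else max
  tsl_of <- setNames(transcripts$tsl, transcripts$transcript_id)
  tibble(intron_id = introns$intron_id,
         tsl_reported = purrr::map_int(introns$transcript_ids, function(ids) {
           v <- tsl_of[ids]
           v <- v[!is.na(v)]
           if (length(v) == 0) NA_integer_ else as.integer(agg(v))
         }))
}

#' Percentage of a gene's protein-coding transcripts containing each intron
#'
#' `100 * (protein-coding parents of the intron) / (protein-coding
#' transcripts of the gene)`, and 0 when the gene has no protein-coding
#' transcript at all (e.g. lncRNA genes).
#'
#' @inheritParams reported_tsl
#' @return Tibble with `intron_id`, `pct_protein_coding_tx`.
#' @export
pct_protein_coding <- function(introns, transcripts) {
  is_pc <- setNames(!is.na(transcripts$biotype) &
                      transcripts$biotype == "protein_coding",
                    transcripts$transcript_id)
  n_pc_gene <- transcripts %>%
    group_by(.data$gene_id) %>%
    summarise(n_pc = sum(!is.na(.data$biotype) & .data$biotype == "protein_coding"),
              .groups = "drop")
  denom <- setNames(n_pc_gene$n_pc, n_pc_gene$gene_id)
  tibble(intron_id = introns$intron_id,
         pct_protein_coding_tx = purrr::map2_dbl(
           introns$transcript_ids, introns$gene_id, function(ids, g) {
             d <- denom[[g]] %||% 0L
             if (is.null(d) || d == 0) return(0)
             100 * sum(is_pc[ids], na.rm = TRUE) / d
           }))
}

#' Flag introns belonging to a MANE Select transcript
#'
#' TRUE when any parent transcript of the intron is the MANE Select model of
#' its gene.
#'
#' @inheritParams reported_tsl
#' @return Tibble with `intron_id`, `in_mane`.
#' @export
flag_mane <- function(introns, transcripts) {
  mane <- setNames(transcripts$is_mane_select, transcripts$transcript_id)
  tibble(intron_id = introns$intron_id,
         in_mane = purrr::map_lgl(introns$transcript_ids,
                                  ~ any(mane[.x], na.rm = TRUE)))
}

#' Index annotated splice sites for exact-position lookup
#'
#' Registers, for every catalogue intron, its donor position under site kind
#' `donor` and its acceptor position under `acceptor`. Several introns may
#' share one site (e.g. alternative donors onto a common acceptor); lookups
#' are exact-position only.
#'
#' @param introns Intron tibble from [build_intron_catalogue()].
#' @return A `splice_site_index`: tibble with columns `chrom`, `strand`,
#'   `pos`, `site_kind`, `intron_id`, `gene_id`.
#' @export
index_splice_sites <- function(introns) {
  assert_columns(introns, c("intron_id", "chrom", "strand", "donor_pos",
                            "acceptor_pos", "gene_id"))
  idx <- bind_rows(
    transmute(introns, chrom = .data$chrom, strand = .data$strand,
              pos = .data$donor_pos, site_kind = "donor",
              intron_id = .data$intron_id, gene_id = .data$gene_id),
    transmute(introns, chrom = .data$chrom, strand = .data$strand,
              pos = .data$acceptor_pos, site_kind = "acceptor",
              intron_id = .data$intron_id, gene_id = .data$gene_id))
  class(idx) <- c("splice_site_index", class(idx))
  idx
}

#' Look up introns whose donor or acceptor sits at an exact position
#'
#' @param index A [index_splice_sites()] result.
#' @param chrom,strand,pos Site coordinates.
#' @param site_kind `"donor"` or `"acceptor"`.
#' @return Character vector of intron ids (empty when no intron is indexed
#'   at the position).
#' @export
lookup_splice_site <- function(index, chrom, strand, pos, site_kind) {
  index$intron_id[index$chrom == chrom & index$strand == strand &
                    index$pos == pos & index$site_kind == site_kind]
}

#' Write / read the intron catalogue interchange TSV
#'
#' The interchange file stores one row per catalogue intron with the
#' `transcript_ids` set collapsed to a comma-separated field; reading it back
#' reproduces the intron tibble field for field.
#'
#' @param introns Intron tibble.
#' @param path Output TSV path.
#' @return `write_intron_tsv()` returns `path` invisibly; `read_intron_tsv()`
#'   returns the intron tibble.
#' @export
write_intron_tsv <- function(introns, path) {
  out <- introns %>%
    mutate(transcript_ids = purrr::map_chr(.data$transcript_ids,
                                           paste, collapse = ","))
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_intron_tsv
#' @export
read_intron_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    intron_id = "c", chrom = "c", strand = "c", start = "i", end = "i",
    donor_pos = "i", acceptor_pos = "i", length = "i", gene_id = "c",
    transcript_ids = "c", n_transcripts = "i", tsl_reported = "i",
    in_mane = "l", pct_protein_coding_tx = "d",
    u2_intron = "l", u12_intron = "l")) %>%
    mutate(transcript_ids = stringr::str_split(.data$transcript_ids, ","))
}
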