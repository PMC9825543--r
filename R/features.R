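#' Fixed-width splice-site scoring windows
#'
#' The donor (5') window spans 9 bp: 3 exonic bases followed by the first 6
#' intronic bases (which start with the near-invariant GT). The acceptor
#' (3') window spans 23 bp: the last 20 intronic bases (ending in AG)
#' followed by 3 exonic bases. Both are strand-oriented; on the `-` strand
#' the genomic interval is mirrored and the extracted sequence must be
#' reverse-complemented. `site_pos` is the first (donor) or last (acceptor)
#' intronic base in transcriptional orientation.
#'
#' @param site_pos Genomic position(s) of the splice site.
#' @param strand `"+"` or `"-"` (vectorised).
#' @return Tibble with `start`, `end` (1-based inclusive; widths 9 and 23).
#' @export
donor_window <- function(site_pos, strand) {
  strand <- rep_len(strand, length(site_pos))
  tibble(start = as.integer(if_else(strand == "-", site_pos - 5L, site_pos - 3L)),
         end = as.integer(if_else(strand == "-", site_pos + 3L, site_pos + 5L)))
}

#' @rdname donor_window
#' @export
acceptor_window <- function(site_pos, strand) {
  strand <- rep_len(strand, length(site_pos))
  tibble(start = as.integer(if_else(strand == "-", site_pos - 3L, site_pos - 19L)),
         end = as.integer(if_else(strand == "-", site_pos + 19L, site_pos + 3L)))
}

#' Proximal intronic windows for conservation and constraint means
#'
#' Two 40-bp windows per intron: the 5' proximal region runs from 5 bp of
#' upstream exon through the first 35 intronic bases; the 3' proximal
#' region from the last 35 intronic bases through 5 bp of downstream exon.
#' For introns shorter than 35 bp the intronic portion truncates at the
#' opposite splice site (flagged in `truncated`).
#'
#' @param introns Catalogue intron tibble.
#' @return Tibble with `intron_id`, `side` (`five_prime`/`three_prime`),
#'   `chrom`, `strand`, `start`, `end`, `truncated`.
#' @export
proximal_windows <- function(introns) {
  intronic <- pmin(35L, introns$length)
  five <- tibble(intron_id = introns$intron_id, side = "five_prime",
                 chrom = introns$chrom, strand = introns$strand,
                 start = as.integer(if_else(introns$strand == "-",
                                            introns$end - intronic + 1L,
                                            introns$start - 5L)),
                 end = as.integer(if_else(introns$strand == "-",
                                          introns$end + 5L,
                                          introns$start + intronic - 1L)),
                 truncated = introns$length < 35L)
  three <- tibble(intron_id = introns$intron_id, side = "three_prime",
                  chrom = introns$chrom, strand = introns$strand,
                  start = as.integer(if_else(introns$strand == "-",
                                             introns$start - 5L,
                                             introns$end - intronic + 1L)),
                  end = as.integer(if_else(introns$strand == "-",
                                           introns$start + intronic - 1L,
                                           introns$end + 5L)),
                  truncated = introns$length < 35L)
  bind_rows(five, three) %>% arrange(.data$intron_id, .data$side)
}

#' Genome sequence source backed by a FASTA file
#'
#' Wraps a FASTA file in the fetch contract used by the sequence-window
#' operations: `fetch(chrom, start, end, strand)` returns the uppercased
#' bases of the 1-based inclusive interval, reverse-complemented on `-`.
#' Windows reaching beyond the contig yield `NA` with a warning.
#'
#' @param path FASTA file path.
#' @return An object of class `genome_source` with elements `fetch` and
#'   `lengths` (named contig lengths).
#' @export
fasta_sequence_source <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- stringr::str_extract(names(seqs), "^\\S+")
  lens <- setNames(Biostrings::width(seqs), names(seqs))
  fetch <- function(chrom, start, end, strand = "+") {
    if (!chrom %in% names(seqs)) {
      warn(sprintf("contig %s not in genome", chrom))
      return(NA_character_)
    }
    if (start < 1 || end > lens[[chrom]]) {
      warn(sprintf("window %s:%d-%d exceeds contig bounds", chrom, start, end))
      return(NA_character_)
    }
    s <- Biostrings::subseq(seqs[[chrom]], start, end)
    if (strand == "-") s <- Biostrings::reverseComplement(s)
    toupper(as.character(s))
  }
  structure(list(fetch = fetch, lengths = lens), class = "genome_source")
}

#' Extract splice-site window sequences
#'
#' Adds the donor 9-mer or acceptor 23-mer sequence (strand-oriented) for a
#' table of splice sites.
#'
#' @param sites Tibble with `chrom`, `pos`, `strand`, `site_kind`
#'   (`"donor"`/`"acceptor"`).
#' @param genome A [fasta_sequence_source()].
#' @return `sites` with added `win_start`, `win_end` and `seq` (`NA` when
#'   the window leaves the contig).
#' @export
splice_site_sequences <- function(sites, genome) {
  assert_columns(sites, c("chrom", "pos", "strand", "site_kind"))
  win_d <- donor_window(sites$pos, sites$strand)
  win_a <- acceptor_window(sites$pos, sites$strand)
  is_d <- sites$site_kind == "donor"
  sites$win_start <- if_else(is_d, win_d$start, win_a$start)
  sites$win_end <- if_else(is_d, win_d$end, win_a$end)
  sites$seq <- purrr::pmap_chr(
    list(sites$chrom, sites$win_start, sites$win_end, sites$strand),
    function(c, s, e, st) genome$fetch(c, s, e, st))
  sites
}

#' Consensus position-weight-matrix splice-site scorer
#'
#' A deterministic log-odds scorer over fixed mammalian consensus base
#' frequencies: higher scores mean the sequence more closely resembles an
#' annotated splice site. `score_donor` expects the 9-bp donor window,
#' `score_acceptor` the 23-bp acceptor window; sequences containing `N` (or
#' `NA`) score `NA`. The scorer satisfies the pluggable scoring contract,
#' so any function pair with the same signature (e.g. a wrapper around an
#' external maximum-entropy model) can be substituted.
#'
#' @return List with functions `score_donor` and `score_acceptor`.
#' @export
pwm_splice_scorer <- function() {
  # rows A,C,G,T; columns = window positions (consensus-style frequencies)
  donor_f <- matrix(c(
    0.33, 0.60, 0.08, 0.001, 0.001, 0.49, 0.71, 0.06, 0.15,
    0.37, 0.13, 0.04, 0.001, 0.001, 0.03, 0.07, 0.05, 0.19,
    0.18, 0.14, 0.81, 0.997, 0.001, 0.45, 0.12, 0.84, 0.20,
    0.12, 0.13, 0.07, 0.001, 0.997, 0.03, 0.10, 0.05, 0.46),
    nrow = 4, byrow = TRUE, dimnames = list(c("A", "C", "G", "T"), NULL))
  pyr <- c(A = 0.10, C = 0.35, G = 0.10, T = 0.45)
  acceptor_f <- cbind(
    matrix(rep(pyr, 18), nrow = 4,
           dimnames = list(c("A", "C", "G", "T"), NULL)),
    c(0.997, 0.001, 0.001, 0.001),   # A of the terminal AG
    c(0.001, 0.001, 0.997, 0.001),   # G of the terminal AG
    matrix(c(0.25, 0.20, 0.45, 0.10), nrow = 4, ncol = 3,
           dimnames = list(c("A", "C", "G", "T"), NULL)))
  donor_f <- sweep(donor_f, 2, colSums(donor_f), "/")
  acceptor_f <- sweep(acceptor_f, 2, colSums(acceptor_f), "/")
  score_with <- function(freq, width) {
    function(seq) {
      if (is.na(seq) || nchar(seq) != width) return(NA_real_)
      bases <- match(strsplit(toupper(seq), "")[[1]], rownames(freq))
      if (anyNA(bases)) return(NA_real_)
      sum(log2(freq[cbind(bases, seq_len(width))] / 0.25))
    }
  }
  list(score_donor = score_with(donor_f, 9L),
       score_acceptor = score_with(acceptor_f, 23L))
}

#' Score donor and acceptor splice sites
#'
#' Extracts the strand-oriented windows with [splice_site_sequences()] and
#' applies a scorer obeying the pluggable contract (default:
#' [pwm_splice_scorer()]).
#'
#' @inheritParams splice_site_sequences
#' @param scorer List with `score_donor` and `score_acceptor` functions.
#' @return `sites` with added `seq` and `score` columns.
#' @export
score_splice_sites <- function(sites, genome, scorer = pwm_splice_scorer()) {
  sites <- splice_site_sequences(sites, genome)
  sites$score <- purrr::map2_dbl(sites$seq, sites$site_kind, function(s, k) {
    if (k == "donor") scorer$score_donor(s) else scorer$score_acceptor(s)
  })
  sites
}

#' Per-base score track from a 3-column TSV
#'
#' Loads a tabular score track (`chrom`, `pos`, `value`; 1-based positions)
#' into the values contract: `values(chrom, start, end)` returns one value
#' per base of the closed interval, `NA` where the track has no data. Used
#' for conservation (phastCons-style, values in `[0, 1]`) and constraint
#' (CDTS-style, values in `[-1, 1]`) tracks.
#'
#' @param x TSV path or a tibble with columns `chrom`, `pos`, `value`.
#' @return Object of class `score_track` with element `values`.
#' @export
track_source_tsv <- function(x) {
  tab <- if (is.character(x)) {
    readr::read_tsv(x, col_types = readr::cols(chrom = "c", pos = "i",
                                               value = "d"))
  } else {
    as_tibble(x)
  }
  assert_columns(tab, c("chrom", "pos", "value"), "score track")
  by_chrom <- split(tab[c("pos", "value")], tab$chrom)
  lookup <- purrr::map(by_chrom, ~ setNames(.x$value, .x$pos))
  values <- function(chrom, start, end) {
    pos <- seq.int(start, end)
    v <- lookup[[chrom]]
    if (is.null(v)) return(rep(NA_real_, length(pos)))
    unname(v[as.character(pos)])
  }
  structure(list(values = values), class = "score_track")
}

#' Per-base score track from a bigWig file
#'
#' Same values contract as [track_source_tsv()], backed by a bigWig track
#' (e.g. a phastCons or CDTS dump).
#'
#' @param path BigWig file path.
#' @return Object of class `score_track` with element `values`.
#' @export
track_source_bigwig <- function(path) {
  gr <- rtracklayer::import(path)
  tab <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr),
                end = GenomicRanges::end(gr),
                value = gr$score) %>%
    dplyr::reframe(pos = seq(.data$start, .data$end),
                   .by = c("chrom", "start", "value")) %>%
    select("chrom", "pos", "value")
  track_source_tsv(tab)
}

#' Mean track score over genomic windows
#'
#' Arithmetic mean over the non-missing bases of each window; `NA` when the
#' whole window is missing from the track (missing bases are excluded, not
#' imputed as zero).
#'
#' @param track A [track_source_tsv()] (or any object with a `values`
#'   function obeying the same contract).
#' @param windows Tibble with `chrom`, `start`, `end`.
#' @return `windows` with an added `mean_score` column.
#' @export
mean_window_score <- function(track, windows) {
  windows$mean_score <- purrr::pmap_dbl(
    list(windows$chrom, windows$start, windows$end),
    function(c, s, e) {
      v <- track$values(c, s, e)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    })
  windows
}

#' Flag introns containing splice-disrupting variant positions
#'
#' TRUE for introns whose closed span contains at least one variant
#' position (e.g. ClinVar pathogenic / likely pathogenic splicing
#' variants). Positions in flanking exons do not count.
#'
#' @param introns Catalogue intron tibble.
#' @param variants Tibble with `chrom`, `pos` (1-based).
#' @return Tibble with `intron_id`, `clinvar`.
#' @export
flag_clinvar <- function(introns, variants) {
  if (is.null(variants) || nrow(variants) == 0) {
    return(tibble(intron_id = introns$intron_id,
                  clinvar = rep(FALSE, nrow(introns))))
  }
  hits <- purrr::map_lgl(seq_len(nrow(introns)), function(i) {
    any(variants$chrom == introns$chrom[i] &
          variants$pos >= introns$start[i] &
          variants$pos <= introns$end[i])
  })
  tibble(intron_id = introns$intron_id, clinvar = hits)
}

#' Join major/minor spliceosome classes onto the catalogue
#'
#' Matches an IAOD-style table by intron coordinates; unmatched introns get
#' `u2_intron = u12_intron = FALSE` (meaning "not categorised"), and an
#' intron marked both U2 and U12 is kept as given with a warning.
#'
#' @param introns Catalogue intron tibble.
#' @param iaod_table Tibble with `chrom`, `start`, `end`, `strand`,
#'   `u2_intron`, `u12_intron`.
#' @return `introns` with `u2_intron` / `u12_intron` replaced by the joined
#'   values.
#' @export
join_spliceosome_class <- function(introns, iaod_table) {
  assert_columns(iaod_table, c("chrom", "start", "end", "strand",
                               "u2_intron", "u12_intron"), "iaod_table")
  both <- iaod_table$u2_intron & iaod_table$u12_intron
  if (any(both)) {
    warn(sprintf("%d intron(s) marked both U2 and U12 in the join table; kept as given",
                 sum(both)))
  }
  introns %>%
    select(-"u2_intron", -"u12_intron") %>%
    left_join(select(iaod_table, "chrom", "start", "end", "strand",
                     "u2_intron", "u12_intron"),
              by = c("chrom", "start", "end", "strand")) %>%
    mutate(u2_intron = dplyr::coalesce(.data$u2_intron, FALSE),
           u12_intron = dplyr::coalesce(.data$u12_intron, FALSE))
}

#' Median gene expression per tissue
#'
#' Median TPM over the (non-excluded) samples of each tissue, per gene.
#'
#' @param expression Long tibble with `gene_id`, `sample_id`, `tpm`.
#' @param samples Sample metadata ([read_sample_metadata()]).
#' @return Tibble with `gene_id`, `tissue`, `median_tpm`.
#' @export
gene_expression_summary <- function(expression, samples) {
  assert_columns(expression, c("gene_id", "sample_id", "tpm"), "expression")
  active <- filter(samples, !.data$excluded)
  expression %>%
    inner_join(select(active, "sample_id", "tissue"), by = "sample_id") %>%
    group_by(.data$gene_id, .data$tissue) %>%
    summarise(median_tpm = median(.data$tpm), .groups = "drop")
}
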