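#' Classify junctions against the annotated intron catalogue
#'
#' Assigns every QC-passing junction to exactly one of seven categories:
#'
#' * `annotated` — both ends exactly match one catalogue intron's span;
#' * `novel_donor` — only the acceptor end matches an annotated acceptor
#'   site (the donor end is unannotated);
#' * `novel_acceptor` — only the donor end matches an annotated donor site;
#' * `novel_exon_skip` — both ends match annotated sites of one gene, the
#'   pair is not an annotated intron, and the span fully contains at least
#'   one internal annotated exon of that gene;
#' * `novel_combo` — as above but containing no complete internal exon;
#' * `ambiguous_gene` — end matches involve different genes, a single
#'   matching end hits sites of several genes, or the only matches are on
#'   the opposite strand (including unknown-strand junctions matching on
#'   both strands);
#' * `unannotated` — neither end matches any annotated splice site.
#'
#' Matching is exact-position: a junction end matches a splice site only at
#' base-pair identity, with no tolerance window. Ends are tested
#' strand-aware (on `+` the span start is the donor end; on `-` the span end
#' is). Junctions with unknown strand (`*`) are tested on both strands and
#' `resolved_strand` is set from the unique strand with annotation matches.
#'
#' @param junctions Junction tibble (`junction_id`, `chrom`, `strand`,
#'   `start`, `end`).
#' @param catalogue An `intron_catalogue` from [build_intron_catalogue()].
#' @param index Optional pre-built [index_splice_sites()] result (built from
#'   the catalogue when omitted).
#' @return Tibble with `junction_id`, `category`, `resolved_strand`, and
#'   list-columns `matched_donor_intron_ids`, `matched_acceptor_intron_ids`,
#'   `annotated_intron_ids`.
#' @export
classify_junctions <- function(junctions, catalogue, index = NULL) {
  assert_columns(junctions, c("junction_id", "chrom", "strand", "start", "end"))
  index <- index %||% index_splice_sites(catalogue$introns)
  internal_exons <- internal_exon_table(catalogue$exons)
  introns <- catalogue$introns

  plus <- match_on_strand(junctions, "+", index, introns, internal_exons)
  minus <- match_on_strand(junctions, "-", index, introns, internal_exons)

  res <- purrr::pmap(list(seq_len(nrow(junctions)), junctions$strand),
                     function(i, s) {
    p <- plus[[i]]; m <- minus[[i]]
    if (s == "+" || s == "-") {
      own <- if (s == "+") p else m
      opp <- if (s == "+") m else p
      if (own$category == "unannotated" && opp$matched) {
        own$category <- "ambiguous_gene"
      }
      own$resolved_strand <- s
      own
    } else {
      if (p$matched && m$matched) {
        list(category = "ambiguous_gene", resolved_strand = "*",
             donor_ids = character(), acceptor_ids = character(),
             annotated_ids = character(), matched = TRUE)
      } else if (p$matched) {
        p$resolved_strand <- "+"; p
      } else if (m$matched) {
        m$resolved_strand <- "-"; m
      } else {
        list(category = "unannotated", resolved_strand = "*",
             donor_ids = character(), acceptor_ids = character(),
             annotated_ids = character(), matched = FALSE)
      }
    }
  })

  tibble(junction_id = junctions$junction_id,
         category = purrr::map_chr(res, "category"),
         resolved_strand = purrr::map_chr(res, "resolved_strand"),
         matched_donor_intron_ids = purrr::map(res, "donor_ids"),
         matched_acceptor_intron_ids = purrr::map(res, "acceptor_ids"),
         annotated_intron_ids = purrr::map(res, "annotated_ids"))
}

#' Seven junction categories
#'
#' @return Character vector of the category names in classification order.
#' @export
junction_categories <- function() {
  c("annotated", "novel_donor", "novel_acceptor", "novel_combo",
    "novel_exon_skip", "ambiguous_gene", "unannotated")
}

# distinct internal exons (neither first nor last of their transcript),
# split by gene for the exon-skip containment test
internal_exon_table <- function(exons) {
  if (nrow(exons) == 0) return(list())
  internal <- exons %>%
    filter(.data$exon_rank > 1L, .data$exon_rank < .data$n_exons) %>%
    distinct(.data$gene_id, .data$chrom, .data$strand, .data$start, .data$end)
  split(internal, internal$gene_id)
}

# per-junction match evaluation under one strand hypothesis; returns a list
# (one element per junction row) of category + matched site sets
match_on_strand <- function(junctions, s, index, introns, internal_exons) {
  n <- nrow(junctions)
  donor_end <- if (s == "+") junctions$start else junctions$end
  acceptor_end <- if (s == "+") junctions$end else junctions$start

  didx <- filter(index, .data$site_kind == "donor", .data$strand == s)
  aidx <- filter(index, .data$site_kind == "acceptor", .data$strand == s)
  dkey <- paste(didx$chrom, didx$pos)
  akey <- paste(aidx$chrom, aidx$pos)
  dmatch <- split(seq_len(nrow(didx)), dkey)
  amatch <- split(seq_len(nrow(aidx)), akey)

  exact_key <- paste(introns$chrom, introns$strand, introns$start, introns$end)
  exact_map <- split(introns$intron_id, exact_key)
  gene_of_intron <- setNames(introns$gene_id, introns$intron_id)

  purrr::map(seq_len(n), function(i) {
    jk_d <- paste(junctions$chrom[i], donor_end[i])
    jk_a <- paste(junctions$chrom[i], acceptor_end[i])
    drows <- dmatch[[jk_d]] %||% integer()
    arows <- amatch[[jk_a]] %||% integer()
    donor_ids <- didx$intron_id[drows]
    acceptor_ids <- aidx$intron_id[arows]
    exact_ids <- exact_map[[paste(junctions$chrom[i], s, junctions$start[i],
                                  junctions$end[i])]] %||% character()
    matched <- length(donor_ids) > 0 || length(acceptor_ids) > 0
    out <- list(donor_ids = donor_ids, acceptor_ids = acceptor_ids,
                annotated_ids = exact_ids, matched = matched,
                resolved_strand = s)
    genes_d <- unique(didx$gene_id[drows])
    genes_a <- unique(aidx$gene_id[arows])

    out$category <- if (length(exact_ids) > 0) {
      "annotated"
    } else if (!matched) {
      "unannotated"
    } else if (length(donor_ids) > 0 && length(acceptor_ids) == 0) {
      # donor end annotated, acceptor end novel
      if (length(genes_d) > 1) "ambiguous_gene" else "novel_acceptor"
    } else if (length(acceptor_ids) > 0 && length(donor_ids) == 0) {
      if (length(genes_a) > 1) "ambiguous_gene" else "novel_donor"
    } else {
      shared <- intersect(genes_d, genes_a)
      if (length(shared) == 0) {
        "ambiguous_gene"
      } else if (span_contains_internal_exon(internal_exons, shared,
                                             junctions$chrom[i], s,
                                             junctions$start[i],
                                             junctions$end[i])) {
        "novel_exon_skip"
      } else {
        "novel_combo"
      }
    }
    out
  })
}

span_contains_internal_exon <- function(internal_exons, genes, chrom, s,
                                        start, end) {
  for (g in genes) {
    ex <- internal_exons[[g]]
    if (is.null(ex)) next
    hit <- ex$chrom == chrom & ex$strand == s &
      ex$start > start & ex$end < end
    if (any(hit)) return(TRUE)
  }
  FALSE
}

#' Retain the database-relevant junction categories
#'
#' Keeps only `annotated`, `novel_donor` and `novel_acceptor` junctions —
#' the categories that can be linked unambiguously to an annotated intron —
#' and tallies the discarded categories.
#'
#' @param classified Output of [classify_junctions()].
#' @return List with `annotated` (tibble of annotated junctions), `novel`
#'   (tibble of novel donor/acceptor junctions) and `discarded_counts`
#'   (named integer vector over the dropped categories).
#' @export
retain_for_database <- function(classified) {
  annotated <- filter(classified, .data$category == "annotated")
  novel <- filter(classified,
                  .data$category %in% c("novel_donor", "novel_acceptor"))
  dropped <- filter(classified,
                    !.data$category %in% c("annotated", "novel_donor",
                                           "novel_acceptor"))
  discarded_counts <- table(factor(dropped$category,
                                   levels = c("novel_combo", "novel_exon_skip",
                                              "ambiguous_gene", "unannotated")))
  list(annotated = annotated, novel = novel,
       discarded_counts = setNames(as.integer(discarded_counts),
                                   names(discarded_counts)))
}
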