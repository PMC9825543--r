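# Independent brute-force classification oracle: plain loops over the full
# catalogue, no index structure, re-deriving the decision rules from the
# category definitions. Deliberately kept free of package internals beyond
# the plain intron/exon tibbles.

oracle_classify_one <- function(chrom, strand, start, end, introns, internal_exons) {
  eval_strand <- function(s) {
    donor_end <- if (s == "+") start else end
    acceptor_end <- if (s == "+") end else start
    exact <- introns$chrom == chrom & introns$strand == s &
      introns$start == start & introns$end == end
    dm <- introns$chrom == chrom & introns$strand == s &
      introns$donor_pos == donor_end
    am <- introns$chrom == chrom & introns$strand == s &
      introns$acceptor_pos == acceptor_end
    matched <- any(dm) || any(am)
    cat <- if (any(exact)) {
      "annotated"
    } else if (!matched) {
      "unannotated"
    } else if (any(dm) && !any(am)) {
      if (length(unique(introns$gene_id[dm])) > 1) "ambiguous_gene"
      else "novel_acceptor"
    } else if (any(am) && !any(dm)) {
      if (length(unique(introns$gene_id[am])) > 1) "ambiguous_gene"
      else "novel_donor"
    } else {
      shared <- intersect(introns$gene_id[dm], introns$gene_id[am])
      if (length(shared) == 0) {
        "ambiguous_gene"
      } else {
        contains <- FALSE
        for (g in shared) {
          ex <- internal_exons[internal_exons$gene_id == g &
                                 internal_exons$chrom == chrom &
                                 internal_exons$strand == s, ]
          if (nrow(ex) > 0 &&
              any(ex$start > start & ex$end < end)) contains <- TRUE
        }
        if (contains) "novel_exon_skip" else "novel_combo"
      }
    }
    list(category = cat, matched = matched)
  }
  if (strand %in% c("+", "-")) {
    own <- eval_strand(strand)
    if (own$category == "unannotated") {
      opp <- eval_strand(if (strand == "+") "-" else "+")
      if (opp$matched) own$category <- "ambiguous_gene"
    }
    list(category = own$category, resolved_strand = strand)
  } else {
    p <- eval_strand("+"); m <- eval_strand("-")
    if (p$matched && m$matched) {
      list(category = "ambiguous_gene", resolved_strand = "*")
    } else if (p$matched) {
      list(category = p$category, resolved_strand = "+")
    } else if (m$matched) {
      list(category = m$category, resolved_strand = "-")
    } else {
      list(category = "unannotated", resolved_strand = "*")
    }
  }
}

oracle_classify <- function(junctions, catalogue) {
  introns <- catalogue$introns
  internal_exons <- catalogue$exons |>
    dplyr::filter(exon_rank > 1, exon_rank < n_exons) |>
    dplyr::distinct(gene_id, chrom, strand, start, end)
  res <- lapply(seq_len(nrow(junctions)), function(i) {
    oracle_classify_one(junctions$chrom[i], junctions$strand[i],
                        junctions$start[i], junctions$end[i],
                        introns, internal_exons)
  })
  tibble::tibble(junction_id = junctions$junction_id,
                 category = vapply(res, `[[`, "", "category"),
                 resolved_strand = vapply(res, `[[`, "", "resolved_strand"))
}

# random junctions mixing exact spans, single-end perturbations,
# site-anchored spans and fully random spans, over all strand codes
random_junctions <- function(n, catalogue, seed = 1) {
  set.seed(seed)
  introns <- catalogue$introns
  rows <- lapply(seq_len(n), function(i) {
    base <- introns[sample(nrow(introns), 1), ]
    kind <- sample(c("exact", "perturb_start", "perturb_end", "cross",
                     "random"), 1)
    start <- base$start; end <- base$end; chrom <- base$chrom
    if (kind == "perturb_start") start <- start + sample(c(-50:-1, 1:50), 1)
    if (kind == "perturb_end") end <- end + sample(c(-50:-1, 1:50), 1)
    if (kind == "cross") {
      other <- introns[sample(nrow(introns), 1), ]
      if (other$chrom == chrom && other$end > start) end <- other$end
    }
    if (kind == "random") {
      start <- sample(5000:80000, 1); end <- start + sample(25:5000, 1)
    }
    if (end <= start) end <- start + 30L
    strand <- sample(c("+", "-", "*"), 1)
    tibble::tibble(chrom = chrom, start = as.integer(start),
                   end = as.integer(end), strand = strand)
  })
  out <- dplyr::bind_rows(rows) |> dplyr::distinct()
  out$junction_id <- junction_coord_id(out$chrom, out$start, out$end,
                                       out$strand)
  out$implied_length <- out$end - out$start + 1L
  out
}
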