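#' Per-sample annotated read counts attributed to catalogue introns
#'
#' Maps each junction classified as `annotated` to the catalogue intron(s)
#' it exactly matches and aggregates read counts per `(intron_id,
#' sample_id)`. These counts are the evidence of annotated intron use that
#' both the pairing co-detection rule and the mis-splicing ratios consume.
#'
#' @param classified Output of [classify_junctions()] (only `annotated` rows
#'   are used).
#' @param counts Long counts tibble (`junction_id`, `sample_id`, `count`).
#' @return Tibble with `intron_id`, `sample_id`, `count`.
#' @export
annotated_intron_counts <- function(classified, counts) {
  ann <- filter(classified, .data$category == "annotated")
  if (nrow(ann) == 0) {
    return(tibble(intron_id = character(), sample_id = character(),
                  count = integer()))
  }
  map <- ann %>%
    select("junction_id", "annotated_intron_ids") %>%
    tidyr::unnest_longer("annotated_intron_ids", values_to = "intron_id")
  map %>%
    inner_join(counts, by = "junction_id",
               relationship = "many-to-many") %>%
    group_by(.data$intron_id, .data$sample_id) %>%
    summarise(count = sum(.data$count), .groups = "drop")
}

#' Candidate parent introns of each novel junction
#'
#' A catalogue intron is a pairing candidate for a novel donor (acceptor)
#' junction when (a) it shares the junction's single annotated splice site —
#' its acceptor (donor) position equals the junction's annotated end on the
#' same contig and strand — and (b) the co-detection rule holds: the intron
#' has at least one annotated read in **every** sample in which the novel
#' junction was observed, pooling samples across all tissues.
#'
#' @param novel Classified novel junctions (rows of [classify_junctions()]
#'   output with category `novel_donor` or `novel_acceptor`).
#' @param counts Long counts tibble for the junctions.
#' @param annot_counts Per-intron annotated counts from
#'   [annotated_intron_counts()].
#' @return Tibble with `junction_id`, `novel_type` and a `candidates`
#'   list-column of intron ids.
#' @export
candidate_parents <- function(novel, counts, annot_counts) {
  if (nrow(novel) == 0) {
    return(tibble(junction_id = character(), novel_type = character(),
                  candidates = list()))
  }
  bad <- !novel$category %in% c("novel_donor", "novel_acceptor")
  if (any(bad)) {
    abort("candidate_parents() expects only novel_donor / novel_acceptor junctions")
  }
  site_ids <- purrr::pmap(list(novel$category,
                               novel$matched_acceptor_intron_ids,
                               novel$matched_donor_intron_ids),
                          function(cat, acc, don) {
                            if (cat == "novel_donor") acc else don
                          })
  no_anchor <- lengths(site_ids) == 0
  if (any(no_anchor)) {
    abort("internal error: novel junction without an annotated end")
  }
  samples_of <- split(counts$sample_id, counts$junction_id)
  detected <- split(paste(annot_counts$intron_id, annot_counts$sample_id),
                    annot_counts$intron_id)
  tibble(junction_id = novel$junction_id,
         novel_type = novel$category,
         candidates = purrr::map2(site_ids, novel$junction_id,
                                  function(cand, jid) {
           smp <- samples_of[[jid]] %||% character()
           if (length(smp) == 0) return(character())
           keep <- purrr::map_lgl(cand, function(ic) {
             all(paste(ic, smp) %in% (detected[[ic]] %||% character()))
           })
           sort(cand[keep])
         }))
}

#' Resolve the unique pairing of novel junctions to parent introns
#'
#' Each novel junction is paired to its parent intron only when exactly one
#' candidate survives [candidate_parents()]: junctions with no candidate are
#' counted unpairable, junctions with two or more are considered ambiguous
#' and discarded outright (no tie-breaking). Pairing is global — one parent
#' per novel junction across all samples and tissues.
#'
#' With `drop_parenting_introns = TRUE`, introns that appear in the
#' candidate set of at least one ambiguous junction and end up parenting no
#' unambiguous novel junction are listed in `dropped_intron_ids`; downstream
#' stages exclude them from the mis-splicing tables. Introns with no novel
#' activity at all are never dropped.
#'
#' @inheritParams candidate_parents
#' @param junctions Junction coordinate tibble (to locate the novel splice
#'   site of each pair).
#' @param introns Catalogue intron tibble.
#' @param drop_parenting_introns Whether to flag introns orphaned by
#'   ambiguity removal (default `TRUE`).
#' @return List with `pairs` — tibble of `novel_junction_id`, `intron_id`,
#'   `novel_type`, `shared_site_pos`, `novel_site_pos` — and `audit`, a list
#'   with `n_paired`, `n_unpairable`, `n_ambiguous`, `dropped_intron_ids`.
#' @export
resolve_pairs <- function(novel, junctions, counts, annot_counts, introns,
                          drop_parenting_introns = TRUE) {
  cand <- candidate_parents(novel, counts, annot_counts)
  ncand <- lengths(cand$candidates)
  paired <- cand[ncand == 1L, , drop = FALSE]
  ambiguous <- cand[ncand >= 2L, , drop = FALSE]

  donor_of <- setNames(introns$donor_pos, introns$intron_id)
  acceptor_of <- setNames(introns$acceptor_pos, introns$intron_id)
  jx <- junctions %>% select("junction_id", "start", "end")
  strand_of <- setNames(novel$resolved_strand, novel$junction_id)

  pairs <- if (nrow(paired) == 0) {
    tibble(novel_junction_id = character(), intron_id = character(),
           novel_type = character(), shared_site_pos = integer(),
           novel_site_pos = integer())
  } else {
    paired %>%
      mutate(intron_id = purrr::map_chr(.data$candidates, 1)) %>%
      left_join(jx, by = "junction_id") %>%
      transmute(novel_junction_id = .data$junction_id,
                intron_id = .data$intron_id,
                novel_type = .data$novel_type,
                shared_site_pos = unname(if_else(
                  .data$novel_type == "novel_donor",
                  acceptor_of[.data$intron_id],
                  donor_of[.data$intron_id])),
                novel_site_pos = novel_end_position(
                  .data$novel_type, strand_of[.data$novel_junction_id],
                  .data$start, .data$end)) %>%
      arrange(.data$intron_id, .data$novel_junction_id)
  }

  dropped <- character()
  if (drop_parenting_introns && nrow(ambiguous) > 0) {
    touched <- unique(unlist(ambiguous$candidates))
    dropped <- sort(setdiff(touched, pairs$intron_id))
  }
  list(pairs = pairs,
       audit = list(n_paired = nrow(paired),
                    n_unpairable = sum(ncand == 0L),
                    n_ambiguous = nrow(ambiguous),
                    dropped_intron_ids = dropped))
}

# position of the unannotated end of a novel junction: the donor end for
# novel_donor events, the acceptor end for novel_acceptor events
novel_end_position <- function(novel_type, strand, start, end) {
  as.integer(ifelse(novel_type == "novel_donor",
                    ifelse(strand == "-", end, start),
                    ifelse(strand == "-", start, end)))
}

#' Invert resolved pairs into the intron -> novel junctions hierarchy
#'
#' @param pairs Pairs tibble from [resolve_pairs()].
#' @return Tibble with `intron_id` and a `novel_junction_ids` list-column;
#'   every novel junction appears under exactly one intron.
#' @export
pairs_to_hierarchy <- function(pairs) {
  if (anyDuplicated(pairs$novel_junction_id)) {
    abort("duplicate novel_junction_id across pairs: each novel junction must have a unique parent")
  }
  if (nrow(pairs) == 0) {
    return(tibble(intron_id = character(), novel_junction_ids = list()))
  }
  pairs %>%
    group_by(.data$intron_id) %>%
    summarise(novel_junction_ids = list(.data$novel_junction_id),
              .groups = "drop")
}
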