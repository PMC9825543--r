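#' Mis-splicing ratio from pooled read counts
#'
#' `MSR = sum(novel reads) / (sum(novel reads) + sum(annotated reads))`,
#' pooling counts across the samples of one tissue before dividing (a
#' ratio of sums, not a mean of per-sample ratios). Under the
#' `"both_sides"` denominator the novel reads of the opposite splice site
#' are added to the denominator as well.
#'
#' @param j_novel Pooled novel junction reads at the measured site.
#' @param s_annotated Pooled annotated intron reads.
#' @param j_other Pooled novel reads of the opposite site (used only when
#'   `denominator = "both_sides"`).
#' @param denominator `"same_side"` (default, the displayed-formula reading)
#'   or `"both_sides"`.
#' @return Numeric ratio in `[0, 1]`; `NA` when the denominator is zero.
#' @export
compute_msr <- function(j_novel, s_annotated, j_other = 0,
                        denominator = c("same_side", "both_sides")) {
  denominator <- match.arg(denominator)
  den <- j_novel + s_annotated +
    if (denominator == "both_sides") j_other else 0
  if_else(den > 0, j_novel / den, NA_real_)
}

#' Percentage of tissue samples in which each entity was detected
#'
#' Detection means at least one read in the sample. The denominator is the
#' full set of tissue samples, detected or not.
#'
#' @param counts Long counts tibble whose first column is the entity id
#'   (e.g. `intron_id` or `junction_id`), plus `sample_id` and `count`.
#' @param sample_ids The samples of the tissue.
#' @return Tibble with the entity id column and `pct_samples`.
#' @export
pct_samples_detected <- function(counts, sample_ids) {
  id_col <- names(counts)[1]
  n <- length(sample_ids)
  if (n == 0) abort("tissue has no samples")
  counts %>%
    filter(.data$sample_id %in% sample_ids, .data$count >= 1) %>%
    group_by(across(all_of(id_col))) %>%
    summarise(pct_samples = 100 * dplyr::n_distinct(.data$sample_id) / n,
              .groups = "drop")
}

#' Mean read count per sample for each entity
#'
#' Two denominator modes: `"all_samples"` divides the pooled count by the
#' number of tissue samples (used for annotated intron coverage);
#' `"detected_samples"` divides by the number of samples with at least one
#' read (used for novel junction coverage). Entities with zero detected
#' samples yield no row in `"detected_samples"` mode.
#'
#' @inheritParams pct_samples_detected
#' @param mode `"all_samples"` or `"detected_samples"`.
#' @return Tibble with the entity id column and `mean_reads`.
#' @export
mean_reads <- function(counts, sample_ids,
                       mode = c("all_samples", "detected_samples")) {
  mode <- match.arg(mode)
  id_col <- names(counts)[1]
  n_all <- length(sample_ids)
  if (n_all == 0) abort("tissue has no samples")
  counts %>%
    filter(.data$sample_id %in% sample_ids, .data$count >= 1) %>%
    group_by(across(all_of(id_col))) %>%
    summarise(mean_reads = if (mode == "all_samples") {
      sum(.data$count) / n_all
    } else {
      sum(.data$count) / dplyr::n_distinct(.data$sample_id)
    }, .groups = "drop")
}

#' Signed splice-site shift distance and frameshift capability
#'
#' For every resolved pair, the distance in base pairs between the novel
#' splice site and the corresponding annotated site of the parent intron
#' (the donor site for novel donor events, the acceptor site for novel
#' acceptor events). The sign is transcriptional: positive means the novel
#' site lies downstream of the annotated site in the direction of
#' transcription. A shift whose absolute value is not a multiple of 3
#' (`|d| mod 3` of 1 or 2) can throw downstream codons out of frame.
#'
#' @param pairs Pairs tibble from [resolve_pairs()].
#' @param introns Catalogue intron tibble.
#' @return Tibble with `novel_junction_id`, `intron_id`, `distance_bp`,
#'   `frameshift`.
#' @export
distance_and_frameshift <- function(pairs, introns) {
  if (nrow(pairs) == 0) {
    return(tibble(novel_junction_id = character(), intron_id = character(),
                  distance_bp = integer(), frameshift = logical()))
  }
  parent <- introns %>%
    select("intron_id", "strand", "donor_pos", "acceptor_pos")
  out <- pairs %>%
    left_join(parent, by = "intron_id") %>%
    mutate(annotated_site = if_else(.data$novel_type == "novel_donor",
                                    .data$donor_pos, .data$acceptor_pos),
           raw = .data$novel_site_pos - .data$annotated_site,
           distance_bp = as.integer(if_else(.data$strand == "-",
                                            -.data$raw, .data$raw)),
           frameshift = abs(.data$distance_bp) %% 3L %in% c(1L, 2L))
  if (any(out$distance_bp == 0L)) {
    abort("internal error: novel splice site coincides with the annotated site")
  }
  select(out, "novel_junction_id", "intron_id", "distance_bp", "frameshift")
}

#' Per-tissue mis-splicing statistics for annotated introns
#'
#' For each tissue and each annotated intron detected in it, pools reads
#' across the tissue's samples and computes the donor- and acceptor-side
#' mis-splicing ratios together with support statistics. A record is
#' emitted only when the intron is detected in the tissue; under the
#' default `detection_rule = "annotated_reads"` detection requires at least
#' one annotated read (which guarantees a positive denominator), while
#' `"any_supporting_reads"` also admits introns seen only through novel
#' junction reads.
#'
#' @param introns Catalogue intron tibble.
#' @param pairs Pairs tibble from [resolve_pairs()].
#' @param counts Long junction counts (`junction_id`, `sample_id`, `count`).
#' @param annot_counts Per-intron annotated counts from
#'   [annotated_intron_counts()].
#' @param samples Sample metadata tibble ([read_sample_metadata()]);
#'   excluded samples are ignored.
#' @param dropped_intron_ids Introns to exclude (e.g. the
#'   `dropped_intron_ids` of the pairing audit).
#' @param msr_denominator Passed to [compute_msr()].
#' @param detection_rule `"annotated_reads"` or `"any_supporting_reads"`.
#' @return Tibble with one row per `(intron_id, tissue)`: `msr_d`, `msr_a`,
#'   `n_samples`, `sum_novel_donor_reads`, `sum_novel_acceptor_reads`,
#'   `sum_annotated_reads`, `pct_samples_detected`, `mean_annotated_reads`.
#' @export
tissue_intron_stats <- function(introns, pairs, counts, annot_counts, samples,
                                dropped_intron_ids = character(),
                                msr_denominator = c("same_side", "both_sides"),
                                detection_rule = c("annotated_reads",
                                                   "any_supporting_reads")) {
  msr_denominator <- match.arg(msr_denominator)
  detection_rule <- match.arg(detection_rule)
  active <- filter(samples, !.data$excluded)
  novel_by_intron <- pairs %>%
    select("novel_junction_id", "intron_id", "novel_type") %>%
    inner_join(counts, by = c(novel_junction_id = "junction_id"))

  purrr::map(split(active$sample_id, active$tissue), function(smp) {
    n_tissue <- length(smp)
    ann <- annot_counts %>%
      filter(.data$sample_id %in% smp) %>%
      group_by(.data$intron_id) %>%
      summarise(sum_annotated_reads = sum(.data$count),
                n_detected = dplyr::n_distinct(.data$sample_id),
                .groups = "drop")
    nov <- novel_by_intron %>%
      filter(.data$sample_id %in% smp) %>%
      group_by(.data$intron_id) %>%
      summarise(
        sum_novel_donor_reads = sum(.data$count[.data$novel_type == "novel_donor"]),
        sum_novel_acceptor_reads = sum(.data$count[.data$novel_type == "novel_acceptor"]),
        .groups = "drop")
    stats <- dplyr::full_join(ann, nov, by = "intron_id") %>%
      mutate(across(c("sum_annotated_reads", "sum_novel_donor_reads",
                      "sum_novel_acceptor_reads", "n_detected"),
                    ~ dplyr::coalesce(.x, 0L)))
    stats <- if (detection_rule == "annotated_reads") {
      filter(stats, .data$sum_annotated_reads >= 1)
    } else {
      filter(stats, .data$sum_annotated_reads + .data$sum_novel_donor_reads +
               .data$sum_novel_acceptor_reads >= 1)
    }
    stats %>%
      mutate(msr_d = compute_msr(.data$sum_novel_donor_reads,
                                 .data$sum_annotated_reads,
                                 .data$sum_novel_acceptor_reads,
                                 msr_denominator),
             msr_a = compute_msr(.data$sum_novel_acceptor_reads,
                                 .data$sum_annotated_reads,
                                 .data$sum_novel_donor_reads,
                                 msr_denominator),
             n_samples = n_tissue,
             pct_samples_detected = 100 * .data$n_detected / n_tissue,
             mean_annotated_reads = .data$sum_annotated_reads / n_tissue) %>%
      select(-"n_detected")
  }) %>%
    bind_rows(.id = "tissue") %>%
    filter(!.data$intron_id %in% dropped_intron_ids) %>%
    select("intron_id", "tissue", "msr_d", "msr_a", "n_samples",
           "sum_novel_donor_reads", "sum_novel_acceptor_reads",
           "sum_annotated_reads", "pct_samples_detected",
           "mean_annotated_reads") %>%
    arrange(.data$tissue, .data$intron_id)
}

#' Per-tissue statistics for paired novel junctions
#'
#' One row per `(novel junction, tissue)` in which the junction was detected
#' (at least one read): percentage of the tissue's samples using the
#' junction, mean reads over the samples where it was detected, the signed
#' splice-site shift distance with its frameshift flag, and the implied
#' intron length.
#'
#' @inheritParams tissue_intron_stats
#' @param junctions Junction coordinate tibble (for implied lengths).
#' @return Tibble with `novel_junction_id`, `intron_id`, `novel_type`,
#'   `tissue`, `pct_samples_used`, `mean_reads_when_detected`,
#'   `distance_bp`, `frameshift`, `implied_length`.
#' @export
tissue_novel_stats <- function(pairs, junctions, counts, samples, introns) {
  active <- filter(samples, !.data$excluded)
  dist <- distance_and_frameshift(pairs, introns)
  base <- pairs %>%
    select("novel_junction_id", "intron_id", "novel_type") %>%
    left_join(dist, by = c("novel_junction_id", "intron_id")) %>%
    left_join(select(junctions, "junction_id", "implied_length"),
              by = c(novel_junction_id = "junction_id"))
  jc <- counts %>% filter(.data$junction_id %in% pairs$novel_junction_id)

  purrr::map(split(active$sample_id, active$tissue), function(smp) {
    n_tissue <- length(smp)
    jc %>%
      filter(.data$sample_id %in% smp) %>%
      group_by(novel_junction_id = .data$junction_id) %>%
      summarise(pct_samples_used = 100 * dplyr::n_distinct(.data$sample_id) / n_tissue,
                mean_reads_when_detected = sum(.data$count) /
                  dplyr::n_distinct(.data$sample_id),
                .groups = "drop")
  }) %>%
    bind_rows(.id = "tissue") %>%
    inner_join(base, by = "novel_junction_id") %>%
    select("novel_junction_id", "intron_id", "novel_type", "tissue",
           "pct_samples_used", "mean_reads_when_detected", "distance_bp",
           "frameshift", "implied_length") %>%
    arrange(.data$tissue, .data$intron_id, .data$novel_junction_id)
}

#' Support-for-novel-annotation filter
#'
#' Returns the novel junctions of a tissue whose sample support reaches
#' `min_pct` percent. Because mis-splicing is a largely random process, a
#' specific novel junction recurring across a high fraction of unrelated
#' samples (e.g. >= 90%) is more plausibly a novel stable transcript than
#' splicing noise.
#'
#' @param novel_stats Output of [tissue_novel_stats()].
#' @param min_pct Minimum `pct_samples_used`, in `[0, 100]`.
#' @param tissue Tissue to filter on (`NULL` = all tissues pooled).
#' @return Character vector of novel junction ids.
#' @export
support_filter <- function(novel_stats, min_pct, tissue = NULL) {
  if (!is.numeric(min_pct) || min_pct < 0 || min_pct > 100) {
    abort("min_pct must lie in [0, 100]")
  }
  out <- novel_stats
  if (!is.null(tissue)) out <- filter(out, .data$tissue %in% !!tissue)
  unique(out$novel_junction_id[out$pct_samples_used >= min_pct])
}
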