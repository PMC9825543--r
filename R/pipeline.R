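#' Run the full junction-to-database pipeline in memory
#'
#' Drives every stage over one set of inputs: builds the intron catalogue
#' from the GTF, reads the junction tables of the non-excluded samples,
#' applies the three quality-control filters, classifies the surviving
#' junctions, retains the annotated / novel donor / novel acceptor
#' categories, pairs each novel junction to its unique parent intron under
#' the co-detection rule, and computes the per-tissue intron and novel
#' junction statistics.
#'
#' @param gtf_path Reference annotation GTF.
#' @param manifest Tibble with `sample_id`, `path` (junction file per
#'   sample), or path to such a TSV (paths then resolved relative to the
#'   manifest's directory).
#' @param samples Sample metadata tibble or TSV path
#'   (see [read_sample_metadata()]).
#' @param blacklist Blacklist tibble, BED path, or `NULL`.
#' @param dialect Junction file dialect (see [read_junctions()]).
#' @param min_length,whitelist,blacklist_mode QC parameters
#'   (see [apply_junction_qc()]).
#' @param tsl_policy Passed to [build_intron_catalogue()].
#' @param msr_denominator,detection_rule Passed to [tissue_intron_stats()].
#' @param drop_parenting_introns Passed to [resolve_pairs()].
#' @return A `splice_build` object: list with `catalogue`, `samples`,
#'   `junctions`, `counts`, `qc_audit`, `classified`, `discarded_counts`,
#'   `pairs`, `pairing_audit`, `intron_stats`, `novel_stats`, `params`.
#' @export
run_splice_pipeline <- function(gtf_path, manifest, samples,
                                blacklist = NULL,
                                dialect = "star_sj",
                                min_length = 25,
                                whitelist = default_chromosomes(),
                                blacklist_mode = "span",
                                tsl_policy = "best",
                                msr_denominator = "same_side",
                                detection_rule = "annotated_reads",
                                drop_parenting_introns = TRUE) {
  if (is.character(samples)) samples <- read_sample_metadata(samples)
  if (is.character(manifest)) {
    base <- dirname(manifest)
    manifest <- readr::read_tsv(manifest, col_types = readr::cols(
      sample_id = "c", path = "c")) %>%
      mutate(path = file.path(base, .data$path))
  }
  if (is.character(blacklist)) blacklist <- read_blacklist_bed(blacklist)

  catalogue <- build_intron_catalogue(gtf_path, tsl_policy = tsl_policy)
  index <- index_splice_sites(catalogue$introns)

  active <- filter(samples, !.data$excluded)
  manifest <- semi_join(manifest, active, by = "sample_id")
  jr <- read_junctions(manifest$path, dialect = dialect,
                       sample_ids = manifest$sample_id)
  qc <- apply_junction_qc(jr$junctions, min_length = min_length,
                          whitelist = whitelist, blacklist = blacklist,
                          blacklist_mode = blacklist_mode)
  counts <- semi_join(jr$counts, qc$junctions, by = "junction_id")

  classified <- classify_junctions(qc$junctions, catalogue, index)
  retained <- retain_for_database(classified)
  annot_counts <- annotated_intron_counts(classified, counts)
  resolved <- resolve_pairs(retained$novel, qc$junctions, counts,
                            annot_counts, catalogue$introns,
                            drop_parenting_introns = drop_parenting_introns)
  intron_stats <- tissue_intron_stats(
    catalogue$introns, resolved$pairs, counts, annot_counts, samples,
    dropped_intron_ids = resolved$audit$dropped_intron_ids,
    msr_denominator = msr_denominator, detection_rule = detection_rule)
  novel_stats <- tissue_novel_stats(resolved$pairs, qc$junctions, counts,
                                    samples, catalogue$introns)

  structure(list(catalogue = catalogue, samples = samples,
                 junctions = qc$junctions, counts = counts,
                 qc_audit = qc$audit, classified = classified,
                 discarded_counts = retained$discarded_counts,
                 pairs = resolved$pairs, pairing_audit = resolved$audit,
                 intron_stats = intron_stats, novel_stats = novel_stats,
                 params = list(min_length = min_length,
                               blacklist_mode = blacklist_mode,
                               tsl_policy = tsl_policy,
                               msr_denominator = msr_denominator,
                               detection_rule = detection_rule,
                               drop_parenting_introns = drop_parenting_introns)),
            class = "splice_build")
}

#' @export
print.splice_build <- function(x, ...) {
  cat(sprintf(paste0(
    "<splice_build>\n",
    "  introns in catalogue: %d\n",
    "  junctions after QC:   %d\n",
    "  novel pairs:          %d (unpairable %d, ambiguous %d)\n",
    "  tissues with stats:   %d\n"),
    nrow(x$catalogue$introns), nrow(x$junctions), nrow(x$pairs),
    x$pairing_audit$n_unpairable, x$pairing_audit$n_ambiguous,
    dplyr::n_distinct(x$intron_stats$tissue)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-tissue intron statistics of a pipeline run
#'
#' @param x A `splice_build` object.
#' @param ... Unused.
#' @return The per-tissue intron statistics tibble (one row per intron and
#'   tissue, with `msr_d`, `msr_a` and support columns).
#' @export
tidy.splice_build <- function(x, ...) {
  as_tibble(x$intron_stats)
}

#' One-row summary of a pipeline run
#'
#' @param x A `splice_build` object.
#' @param ... Unused.
#' @return A one-row tibble: catalogue size, QC-passing junction count,
#'   category counts for the retained classes, pairing audit counts and the
#'   overall median mis-splicing ratios.
#' @export
glance.splice_build <- function(x, ...) {
  cat_counts <- table(factor(x$classified$category,
                             levels = junction_categories()))
  tibble(n_introns_catalogue = nrow(x$catalogue$introns),
         n_junctions_qc = nrow(x$junctions),
         n_annotated = as.integer(cat_counts[["annotated"]]),
         n_novel_donor = as.integer(cat_counts[["novel_donor"]]),
         n_novel_acceptor = as.integer(cat_counts[["novel_acceptor"]]),
         n_paired = x$pairing_audit$n_paired,
         n_unpairable = x$pairing_audit$n_unpairable,
         n_ambiguous = x$pairing_audit$n_ambiguous,
         median_msr_d = median(x$intron_stats$msr_d, na.rm = TRUE),
         median_msr_a = median(x$intron_stats$msr_a, na.rm = TRUE))
}
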