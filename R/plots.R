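#' Plot the per-tissue distribution of mis-splicing ratios
#'
#' Log-scaled histograms of `MSR_D` and `MSR_A` per tissue. Ratios of
#' exactly zero (accurate splicing, typically the modal value) are shown as
#' a separate annotated count because they have no place on a log axis.
#'
#' @param intron_stats Output of [tissue_intron_stats()].
#' @return A ggplot object.
#' @export
plot_msr_distribution <- function(intron_stats) {
  long <- intron_stats %>%
    tidyr::pivot_longer(c("msr_d", "msr_a"), names_to = "site",
                        values_to = "msr") %>%
    mutate(site = if_else(.data$site == "msr_d", "donor (MSR_D)",
                          "acceptor (MSR_A)"))
  nz <- filter(long, .data$msr > 0)
  ggplot2::ggplot(nz, ggplot2::aes(x = .data$msr, fill = .data$site)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.7,
                            position = "identity") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~tissue) +
    ggplot2::labs(x = "mis-splicing ratio (log scale, zeros omitted)",
                  y = "introns", fill = NULL,
                  subtitle = sprintf("%d of %d records are exactly zero",
                                     sum(long$msr == 0), nrow(long))) +
    ggplot2::theme_minimal()
}

#' Plot junction classification category counts
#'
#' @param classified Output of [classify_junctions()].
#' @return A ggplot object.
#' @export
plot_category_counts <- function(classified) {
  tab <- classified %>%
    count(category = factor(.data$category, levels = junction_categories()))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "junctions") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot sample-support of novel junctions against their shift distance
#'
#' Highlights high-support junctions (candidate novel transcripts) against
#' the low-support background expected from stochastic mis-splicing.
#'
#' @param novel_stats Output of [tissue_novel_stats()].
#' @param support_threshold Horizontal reference line (percent).
#' @return A ggplot object.
#' @export
plot_novel_support <- function(novel_stats, support_threshold = 90) {
  ggplot2::ggplot(novel_stats,
                  ggplot2::aes(x = .data$distance_bp,
                               y = .data$pct_samples_used,
                               colour = .data$novel_type)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = support_threshold, linetype = 2) +
    ggplot2::facet_wrap(~tissue) +
    ggplot2::labs(x = "novel site distance (bp, transcriptional sign)",
                  y = "% samples using the junction", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot a pipeline run
#'
#' Dispatches to [plot_msr_distribution()] (`type = "msr"`, default),
#' [plot_category_counts()] (`type = "categories"`) or
#' [plot_novel_support()] (`type = "support"`).
#'
#' @param object A `splice_build`.
#' @param type One of `"msr"`, `"categories"`, `"support"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.splice_build <- function(object,
                                  type = c("msr", "categories", "support"),
                                  ...) {
  type <- match.arg(type)
  switch(type,
         msr = plot_msr_distribution(object$intron_stats),
         categories = plot_category_counts(object$classified),
         support = plot_novel_support(object$novel_stats))
}
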