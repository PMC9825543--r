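#' Default chromosome whitelist
#'
#' The primary assembled chromosomes of a human-style reference:
#' `chr1`..`chr22`, `chrX` and `chrY`. Junctions on unplaced or unlocalized
#' scaffolds (and on `chrM`) are outside this set and removed by
#' [filter_chromosomes()].
#'
#' @return Character vector of contig names.
#' @export
default_chromosomes <- function() {
  c(paste0("chr", 1:22), "chrX", "chrY")
}

#' Build a stable junction identifier from coordinates
#'
#' Identifiers are coordinate-derived (`chrom:start-end:strand`) so that two
#' runs over the same input always agree, which underpins the determinism of
#' the whole pipeline.
#'
#' @param chrom,start,end,strand Coordinate vectors (1-based inclusive span).
#' @return Character vector of identifiers.
#' @export
junction_coord_id <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d:%s", chrom, as.integer(start), as.integer(end), strand)
}

intron_coord_id <- function(chrom, start, end, strand, gene_id) {
  sprintf("%s:%d-%d:%s@%s", chrom, as.integer(start), as.integer(end), strand, gene_id)
}

# strand flip helper
flip_strand <- function(strand) {
  dplyr::case_when(strand == "+" ~ "-", strand == "-" ~ "+", TRUE ~ strand)
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
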