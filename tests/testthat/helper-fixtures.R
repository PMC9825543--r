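# Small hand-built annotation fixtures used across test files.

# two-gene catalogue written as a GTF in a temp file; mirrors the package's
# documented Ensembl attribute dialect
toy_gtf_path <- function() {
  system.file("extdata", "toy.gtf", package = "intronaut")
}

toy_catalogue <- function() {
  build_intron_catalogue(toy_gtf_path())
}

# junction tibble from a compact coordinate spec "chrom:start-end:strand"
make_junctions <- function(...) {
  specs <- c(...)
  m <- stringr::str_match(specs, "^([^:]+):(\\d+)-(\\d+):(.+)$")
  tibble::tibble(chrom = m[, 2],
                 start = as.integer(m[, 3]),
                 end = as.integer(m[, 4]),
                 strand = m[, 5]) |>
    dplyr::mutate(junction_id = junction_coord_id(chrom, start, end, strand),
                  implied_length = end - start + 1L)
}

make_counts <- function(junctions, sample_ids, count = 5L) {
  tidyr::crossing(junction_id = junctions$junction_id,
                  sample_id = sample_ids) |>
    dplyr::mutate(count = count)
}

# a moderately sized random catalogue (~50 introns) built through the
# synthetic generator with all plants disabled
random_catalogue_gtf <- function(seed = 7, n_genes = 15) {
  dir <- file.path(tempdir(), sprintf("cat_%d_%d", seed, n_genes))
  if (!file.exists(file.path(dir, "annotation.gtf"))) {
    cfg <- simulation_config(
      n_genes = n_genes, n_tissues = 1, samples_per_tissue = 2,
      n_excluded = 0,
      planted = list(short = 0, scaffold = 0, blacklist = 0, combo = 0,
                     exon_skip = 0, gene_ambiguous = 0, unannotated = 0,
                     ambiguous = 0, unpairable = 0,
                     high_support = list(n = 0, tissue = 1, pct = 90)))
    simulate_splicing_dataset(cfg, seed = seed, out_dir = dir)
  }
  file.path(dir, "annotation.gtf")
}
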