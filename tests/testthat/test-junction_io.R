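write_star_file <- function(rows, path) {
  readr::write_tsv(rows, path, col_names = FALSE)
  path
}

test_that("sample metadata parsing enforces uniqueness and boolean tokens", {
  p <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(sample_id = c("s1", "s2", "s3"),
                                  tissue = "brain",
                                  excluded = c("FALSE", "FALSE", "TRUE")), p)
  meta <- read_sample_metadata(p)
  expect_equal(sum(!meta$excluded), 2)

  readr::write_tsv(tibble::tibble(sample_id = c("s1", "s1"),
                                  tissue = "brain", excluded = "FALSE"), p)
  expect_error(read_sample_metadata(p), "s1")

  readr::write_tsv(tibble::tibble(sample_id = "s1", tissue = "brain",
                                  excluded = "maybe"), p)
  expect_error(read_sample_metadata(p), "maybe")

  readr::write_tsv(tibble::tibble(sample_id = character(),
                                  tissue = character(),
                                  excluded = character()), p)
  expect_warning(empty <- read_sample_metadata(p), "no samples")
  expect_equal(nrow(empty), 0)
})

test_that("STAR files merge by coordinates and decode strand", {
  f1 <- write_star_file(tibble::tibble(
    chrom = "chr1", start = 201L, end = 300L, strand = 1L, motif = 1L,
    annotated = 1L, n_unique = 5L, n_multi = 0L, overhang = 20L),
    tempfile())
  f2 <- write_star_file(tibble::tibble(
    chrom = c("chr1", "chr2"), start = c(201L, 900L), end = c(300L, 1000L),
    strand = c(1L, 0L), motif = 1L, annotated = 1L,
    n_unique = c(7L, 3L), n_multi = 0L, overhang = 20L), tempfile())
  jr <- read_junctions(c(f1, f2), dialect = "star_sj",
                       sample_ids = c("s1", "s2"))
  expect_equal(nrow(jr$junctions), 2)
  shared <- jr$counts[jr$counts$junction_id == "chr1:201-300:+", ]
  expect_equal(sort(shared$count), c(5L, 7L))
  # strand code 0 becomes unknown
  expect_equal(jr$junctions$strand[jr$junctions$chrom == "chr2"], "*")
  # duplicate sample ids in the manifest are a hard error, never summed
  expect_error(read_junctions(c(f1, f1), dialect = "star_sj",
                              sample_ids = c("s1", "s1")), "duplicate")
})

test_that("BED junctions convert from 0-based half-open coordinates", {
  p <- tempfile(fileext = ".bed")
  readr::write_tsv(tibble::tibble(a = "chr1", b = 200L, c = 300L, d = ".",
                                  e = 5, f = "+"), p, col_names = FALSE)
  jr <- read_junctions(p, dialect = "bed", sample_ids = "s1")
  expect_equal(jr$junctions$start, 201L)
  expect_equal(jr$junctions$end, 300L)
})

test_that("tsv_matrix dialect reads a coordinate file plus count triplets", {
  coords <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(chrom = c("chr1", "chr1"),
                                  start = c(201L, 501L),
                                  end = c(300L, 600L),
                                  strand = c("+", "-")), coords)
  trip <- tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(junction = c(1L, 1L, 2L),
                                  sample_id = c("s1", "s2", "s1"),
                                  count = c(4, 6, 2)), trip)
  jr <- read_junctions(coords, dialect = "tsv_matrix", counts_path = trip)
  expect_equal(nrow(jr$junctions), 2)
  expect_equal(sum(jr$counts$count), 12L)
})

test_that("length filter keeps 25 bp and removes 24 bp implied introns", {
  j <- make_junctions("chr1:100-123:+",   # 24 bp
                      "chr1:100-124:+",   # 25 bp
                      "chr1:100-200:+")
  kept <- filter_min_length(j)
  expect_equal(removed_count(kept), 1L)
  expect_false("chr1:100-123:+" %in% kept$junction_id)
  expect_true("chr1:100-124:+" %in% kept$junction_id)
  expect_error(filter_min_length(j, min_length = 0), "min_length")
  empty <- filter_min_length(j[0, ])
  expect_equal(removed_count(empty), 0L)
})

test_that("chromosome whitelist removes scaffolds and chrM but keeps chrX", {
  j <- make_junctions("chr1_KI270706v1_random:100-200:+",
                      "chrX:100-200:+", "chrM:100-200:+")
  kept <- filter_chromosomes(j)
  expect_equal(kept$chrom, "chrX")
  expect_equal(removed_count(kept), 2L)
})

test_that("blacklist overlap uses closed intervals; abutting spans survive", {
  j <- make_junctions("chr1:201-300:+", "chr1:301-400:+")
  bl <- tibble::tibble(chrom = "chr1", start = 250L, end = 260L)
  kept <- filter_blacklist(j, bl)
  expect_equal(kept$junction_id, "chr1:301-400:+")
  bl2 <- tibble::tibble(chrom = "chr1", start = 301L, end = 400L)
  kept2 <- filter_blacklist(make_junctions("chr1:201-300:+"), bl2)
  expect_equal(removed_count(kept2), 0L)
  expect_equal(removed_count(filter_blacklist(j, NULL)), 0L)
  # ends mode only inspects the two boundary bases
  j3 <- make_junctions("chr1:201-300:+")
  bl3 <- tibble::tibble(chrom = "chr1", start = 240L, end = 260L)
  expect_equal(removed_count(filter_blacklist(j3, bl3, mode = "ends")), 0L)
  bl4 <- tibble::tibble(chrom = "chr1", start = 295L, end = 305L)
  expect_equal(removed_count(filter_blacklist(j3, bl4, mode = "ends")), 1L)
})

test_that("the three QC filters commute and conserve junction counts", {
  set.seed(11)
  j <- dplyr::bind_rows(
    make_junctions(sprintf("chr%d:%d-%d:+", sample(1:3, 40, TRUE),
                           s <- sample(1000:5000, 40),
                           s + sample(10:500, 40))),
    make_junctions("chrUn_x:100-200:+", "chr1:100-110:+"))
  bl <- tibble::tibble(chrom = "chr1", start = 2000L, end = 2500L)
  orders <- list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))
  filters <- list(function(x) filter_min_length(x),
                  function(x) filter_chromosomes(x),
                  function(x) filter_blacklist(x, bl))
  results <- lapply(orders, function(o) {
    out <- j
    for (k in o) {
      prev <- nrow(out)
      out <- filters[[k]](out)
      expect_equal(prev, nrow(out) + removed_count(out))
    }
    sort(out$junction_id)
  })
  expect_equal(results[[1]], results[[2]])
  expect_equal(results[[1]], results[[3]])
})
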