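metric_fixture <- function() {
  introns <- tibble::tibble(
    intron_id = "I1", chrom = "chr1", strand = "+",
    start = 201L, end = 300L, donor_pos = 201L, acceptor_pos = 300L,
    length = 100L, gene_id = "G1", transcript_ids = list("T1"),
    n_transcripts = 1L)
  samples <- tibble::tibble(sample_id = c("s1", "s2"), tissue = "brain",
                            excluded = FALSE)
  list(introns = introns, samples = samples)
}

test_that("MSR is a pooled ratio of sums, not a mean of per-sample ratios", {
  fx <- metric_fixture()
  pairs <- tibble::tibble(novel_junction_id = "n1", intron_id = "I1",
                          novel_type = "novel_donor",
                          shared_site_pos = 300L, novel_site_pos = 251L)
  # one sample: s = 9, j = 1 -> MSR_D = 0.1, MSR_A = 0
  counts <- tibble::tibble(junction_id = "n1", sample_id = "s1", count = 1L)
  annot <- tibble::tibble(intron_id = "I1", sample_id = "s1", count = 9L)
  one <- tissue_intron_stats(fx$introns, pairs, counts, annot,
                             fx$samples[1, ])
  expect_equal(one$msr_d, 0.1)
  expect_equal(one$msr_a, 0)
  # two samples (s1: s=10, j=0), (s2: s=10, j=10) -> pooled 10/30
  counts2 <- tibble::tibble(junction_id = "n1", sample_id = "s2", count = 10L)
  annot2 <- tibble::tibble(intron_id = "I1", sample_id = c("s1", "s2"),
                           count = 10L)
  two <- tissue_intron_stats(fx$introns, pairs, counts2, annot2, fx$samples)
  expect_equal(two$msr_d, 10 / 30)
  # prose reading: both sides pooled into the denominator
  expect_equal(compute_msr(10, 20, j_other = 5, denominator = "both_sides"),
               10 / 35)
})

test_that("no record is emitted without annotated detection; zero law is exact", {
  fx <- metric_fixture()
  empty_pairs <- tibble::tibble(novel_junction_id = character(),
                                intron_id = character(),
                                novel_type = character(),
                                shared_site_pos = integer(),
                                novel_site_pos = integer())
  # no annotated reads at all -> absent
  none <- tissue_intron_stats(fx$introns, empty_pairs,
                              tibble::tibble(junction_id = character(),
                                             sample_id = character(),
                                             count = integer()),
                              tibble::tibble(intron_id = character(),
                                             sample_id = character(),
                                             count = integer()),
                              fx$samples)
  expect_equal(nrow(none), 0)
  # annotated reads, no novel children -> exactly zero
  annot <- tibble::tibble(intron_id = "I1", sample_id = "s1", count = 4L)
  z <- tissue_intron_stats(fx$introns, empty_pairs,
                           tibble::tibble(junction_id = character(),
                                          sample_id = character(),
                                          count = integer()),
                           annot, fx$samples)
  expect_identical(z$msr_d, 0)
  expect_identical(z$msr_a, 0)
})

test_that("MSR is invariant under uniform count scaling", {
  fx <- metric_fixture()
  pairs <- tibble::tibble(novel_junction_id = "n1", intron_id = "I1",
                          novel_type = "novel_donor",
                          shared_site_pos = 300L, novel_site_pos = 251L)
  counts <- tibble::tibble(junction_id = "n1", sample_id = c("s1", "s2"),
                           count = c(3L, 7L))
  annot <- tibble::tibble(intron_id = "I1", sample_id = c("s1", "s2"),
                          count = c(20L, 40L))
  a <- tissue_intron_stats(fx$introns, pairs, counts, annot, fx$samples)
  b <- tissue_intron_stats(fx$introns, pairs,
                           dplyr::mutate(counts, count = count * 13L),
                           dplyr::mutate(annot, count = count * 13L),
                           fx$samples)
  expect_equal(a$msr_d, b$msr_d)
  # with equal per-sample annotated depth, the pooled MSR equals the
  # depth-weighted mean of per-sample ratios
  per_sample <- c(3 / 23, 7 / 47)
  w <- c(23, 47) / 70
  expect_equal(a$msr_d, sum(w * per_sample))
})

test_that("detection percentages and mean reads follow their denominators", {
  counts <- tibble::tibble(id = "x", sample_id = c("s1", "s3"),
                           count = c(4L, 2L))
  pct <- pct_samples_detected(counts, c("s1", "s2", "s3", "s4"))
  expect_equal(pct$pct_samples, 50)
  expect_equal(pct_samples_detected(counts, c("s1", "s3"))$pct_samples, 100)
  # counts {4, 0, 2}: all-samples mean 2, detected-samples mean 3
  expect_equal(mean_reads(counts, c("s1", "s2", "s3"))$mean_reads, 2)
  expect_equal(mean_reads(counts, c("s1", "s2", "s3"),
                          mode = "detected_samples")$mean_reads, 3)
  one <- tibble::tibble(id = "x", sample_id = "s1", count = 7L)
  expect_equal(mean_reads(one, "s1")$mean_reads, 7)
  expect_equal(mean_reads(one, "s1", "detected_samples")$mean_reads, 7)
  # naive per-sample scan oracle on random counts
  set.seed(4)
  rc <- tibble::tibble(id = "y", sample_id = sprintf("s%d", 1:20),
                       count = rpois(20, 2)) |> dplyr::filter(count > 0)
  got <- pct_samples_detected(rc, sprintf("s%d", 1:20))$pct_samples
  expect_equal(got, 100 * sum(rc$count >= 1) / 20)
})

test_that("frameshift flag is |distance| mod 3 in {1,2}, exhaustively", {
  introns <- tibble::tibble(
    intron_id = "I1", chrom = "chr1", strand = "+",
    start = 1001L, end = 2000L, donor_pos = 1001L, acceptor_pos = 2000L,
    length = 1000L, gene_id = "G1")
  d <- c(-300:-1, 1:300)
  pairs <- tibble::tibble(
    novel_junction_id = sprintf("n%d", seq_along(d)),
    intron_id = "I1", novel_type = "novel_donor",
    shared_site_pos = 2000L, novel_site_pos = 1001L + d)
  got <- distance_and_frameshift(pairs, introns)
  expect_equal(got$distance_bp, d)
  expect_equal(got$frameshift, abs(d) %% 3 %in% c(1, 2))
  expect_false(any(got$frameshift[abs(d) %% 3 == 0]))
  # transcriptional sign flips on the minus strand
  introns_m <- dplyr::mutate(introns, strand = "-", donor_pos = 2000L,
                             acceptor_pos = 1001L)
  pairs_m <- tibble::tibble(novel_junction_id = "n1", intron_id = "I1",
                            novel_type = "novel_donor",
                            shared_site_pos = 1001L, novel_site_pos = 1994L)
  got_m <- distance_and_frameshift(pairs_m, introns_m)
  expect_equal(got_m$distance_bp, 6L)   # 6 bp downstream = towards lower coords
  # a zero distance is structurally impossible and caught
  bad <- dplyr::mutate(pairs_m, novel_site_pos = 2000L)
  expect_error(distance_and_frameshift(bad, introns_m), "internal error")
})

test_that("support filter selects by per-tissue sample percentage", {
  ns <- tibble::tibble(novel_junction_id = c("n1", "n2", "n3"),
                       intron_id = "I1", novel_type = "novel_donor",
                       tissue = c("brain", "brain", "liver"),
                       pct_samples_used = c(90, 40, 95),
                       mean_reads_when_detected = 2,
                       distance_bp = 5L, frameshift = TRUE,
                       implied_length = 80L)
  expect_equal(support_filter(ns, 90, tissue = "brain"), "n1")
  expect_setequal(support_filter(ns, 0, tissue = "brain"), c("n1", "n2"))
  expect_setequal(support_filter(ns, 85), c("n1", "n3"))
  expect_error(support_filter(ns, 101), "min_pct")
})
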