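test_that("window arithmetic matches the stated extents on both strands", {
  # donor 9-mer: 3 exonic + 6 intronic
  expect_equal(as.list(donor_window(201L, "+")), list(start = 198L, end = 206L))
  expect_equal(as.list(donor_window(300L, "-")), list(start = 295L, end = 303L))
  # acceptor 23-mer: 20 intronic + 3 exonic
  expect_equal(as.list(acceptor_window(300L, "+")),
               list(start = 281L, end = 303L))
  expect_equal(as.list(acceptor_window(201L, "-")),
               list(start = 198L, end = 220L))
  # widths are constant whatever the coordinates
  set.seed(2)
  pos <- sample(1000:100000, 50)
  strands <- sample(c("+", "-"), 50, TRUE)
  dw <- donor_window(pos, strands)
  aw <- acceptor_window(pos, strands)
  expect_true(all(dw$end - dw$start + 1L == 9L))
  expect_true(all(aw$end - aw$start + 1L == 23L))
})

test_that("proximal windows span 5+35 and 35+5 bp, mirrored across strands", {
  introns <- tibble::tibble(
    intron_id = c("p", "m"), chrom = "chr1", strand = c("+", "-"),
    start = 201L, end = 300L, donor_pos = c(201L, 300L),
    acceptor_pos = c(300L, 201L), length = 100L, gene_id = "G")
  w <- proximal_windows(introns)
  wp <- w[w$intron_id == "p", ]
  expect_equal(wp$start[wp$side == "five_prime"], 196L)
  expect_equal(wp$end[wp$side == "five_prime"], 235L)
  expect_equal(wp$start[wp$side == "three_prime"], 266L)
  expect_equal(wp$end[wp$side == "three_prime"], 305L)
  wm <- w[w$intron_id == "m", ]
  expect_equal(wm$start[wm$side == "five_prime"], 266L)
  expect_equal(wm$end[wm$side == "five_prime"], 305L)
  expect_equal(wm$start[wm$side == "three_prime"], 196L)
  expect_equal(wm$end[wm$side == "three_prime"], 235L)
  expect_true(all(w$end - w$start + 1L == 40L))
  expect_false(any(w$truncated))
  # short introns truncate at the opposite splice site
  short <- dplyr::mutate(introns[1, ], end = 230L, length = 30L,
                         acceptor_pos = 230L)
  ws <- proximal_windows(short)
  expect_true(all(ws$truncated))
  expect_equal(ws$end[ws$side == "five_prime"], 230L)
})

test_that("strand mirror: a junction on the reverse complement yields identical window sequences", {
  set.seed(5)
  L <- 600L
  fwd <- paste(sample(c("A", "C", "G", "T"), L, TRUE), collapse = "")
  rev <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
  fa <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(fwdchr = fwd, revchr = rev)), fa)
  genome <- fasta_sequence_source(fa)
  # donor at D on fwdchr:+ corresponds to L - D + 1 on revchr:-
  D <- 201L
  s_fwd <- splice_site_sequences(
    tibble::tibble(chrom = "fwdchr", pos = D, strand = "+",
                   site_kind = "donor"), genome)$seq
  s_rev <- splice_site_sequences(
    tibble::tibble(chrom = "revchr", pos = L - D + 1L, strand = "-",
                   site_kind = "donor"), genome)$seq
  expect_equal(s_fwd, s_rev)
  a_fwd <- splice_site_sequences(
    tibble::tibble(chrom = "fwdchr", pos = 300L, strand = "+",
                   site_kind = "acceptor"), genome)$seq
  a_rev <- splice_site_sequences(
    tibble::tibble(chrom = "revchr", pos = L - 300L + 1L, strand = "-",
                   site_kind = "acceptor"), genome)$seq
  expect_equal(a_fwd, a_rev)
  # out-of-bounds windows are absent with a warning
  expect_warning(oob <- genome$fetch("fwdchr", L - 3L, L + 6L), "bounds")
  expect_true(is.na(oob))
})

test_that("the consensus scorer rewards canonical sites and passes N through as absent", {
  sc <- pwm_splice_scorer()
  canonical <- "CAGGTAAGT"
  weak <- "TTTTTTTTT"
  expect_gt(sc$score_donor(canonical), sc$score_donor(weak))
  expect_identical(sc$score_donor(canonical), sc$score_donor(canonical))
  expect_true(is.na(sc$score_donor("CAGGTANGT")))
  expect_true(is.na(sc$score_donor(NA_character_)))
  acc <- paste0(strrep("T", 12), strrep("C", 6), "AG", "GTC")
  expect_gt(sc$score_acceptor(acc), sc$score_acceptor(strrep("A", 23)))
  expect_true(is.na(sc$score_acceptor("TOO SHORT")))
})

test_that("track means ignore missing bases and respect track bounds", {
  tr <- track_source_tsv(tibble::tibble(
    chrom = "chr1", pos = c(101:110, 116:120),
    value = c(rep(0.5, 10), rep(1, 5))))
  w <- tibble::tibble(chrom = "chr1", start = c(101L, 111L, 101L),
                      end = c(110L, 115L, 120L))
  got <- mean_window_score(tr, w)
  expect_equal(got$mean_score[1], 0.5)       # constant track
  expect_true(is.na(got$mean_score[2]))      # fully missing window
  expect_equal(got$mean_score[3], (10 * 0.5 + 5 * 1) / 15)  # missing excluded
  expect_true(all(got$mean_score >= 0.5 - 1e-12 |
                    is.na(got$mean_score)))
})

test_that("variant containment flags intronic positions only", {
  introns <- toy_catalogue()$introns
  target <- introns[introns$start == 201, ]
  flags <- flag_clinvar(introns, tibble::tibble(chrom = "chr1", pos = 250L))
  expect_true(flags$clinvar[flags$intron_id == target$intron_id])
  flags2 <- flag_clinvar(introns, tibble::tibble(chrom = "chr1", pos = 301L))
  expect_false(any(flags2$clinvar))
  flags3 <- flag_clinvar(introns, tibble::tibble(chrom = character(),
                                                 pos = integer()))
  expect_false(any(flags3$clinvar))
})

test_that("spliceosome classes join by coordinates with FALSE defaults", {
  introns <- toy_catalogue()$introns
  iaod <- tibble::tibble(chrom = "chr1", start = 201L, end = 300L,
                         strand = "+", u2_intron = FALSE, u12_intron = TRUE)
  got <- join_spliceosome_class(introns, iaod)
  hit <- got[got$start == 201 & got$chrom == "chr1", ]
  expect_true(hit$u12_intron)
  expect_false(hit$u2_intron)
  rest <- got[!(got$start == 201 & got$chrom == "chr1"), ]
  expect_false(any(rest$u2_intron | rest$u12_intron))
  both <- dplyr::mutate(iaod, u2_intron = TRUE)
  expect_warning(join_spliceosome_class(introns, both), "both U2 and U12")
})

test_that("expression summary is the per-tissue median over active samples", {
  samples <- tibble::tibble(sample_id = c("s1", "s2", "s3", "s4"),
                            tissue = c("brain", "brain", "brain", "brain"),
                            excluded = c(FALSE, FALSE, FALSE, TRUE))
  expr <- tibble::tibble(gene_id = "G1", sample_id = c("s1", "s2", "s3", "s4"),
                         tpm = c(1, 3, 100, 1e6))
  got <- gene_expression_summary(expr, samples)
  expect_equal(got$median_tpm, 3)
  even <- gene_expression_summary(
    tibble::tibble(gene_id = "G1", sample_id = c("s1", "s2"), tpm = c(2, 4)),
    samples)
  expect_equal(even$median_tpm, 3)   # midpoint convention
})

test_that("bigWig tracks honour the same values contract as tabular tracks", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101:120, 101:120),
                               score = rep(c(0.25, 0.75), 10))
  GenomeInfoDb::seqlengths(gr) <- c(chr1 = 1000)
  bw <- tempfile(fileext = ".bw")
  rtracklayer::export(gr, bw)
  tr <- track_source_bigwig(bw)
  w <- tibble::tibble(chrom = "chr1", start = 101L, end = 120L)
  expect_equal(mean_window_score(tr, w)$mean_score, 0.5)
  expect_true(all(is.na(tr$values("chr1", 500, 510))))
})
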