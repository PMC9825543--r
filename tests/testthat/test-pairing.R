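# A compact hand-built scenario: one gene, introns A ([201,300]) and
# B ([251,300]) share acceptor 300 on +; intron C ([401,500]) stands alone.
pairing_fixture <- function() {
  introns <- tibble::tibble(
    intron_id = c("A", "B", "C"),
    chrom = "chr1", strand = "+",
    start = c(201L, 251L, 401L), end = c(300L, 300L, 500L),
    donor_pos = c(201L, 251L, 401L), acceptor_pos = c(300L, 300L, 500L),
    length = c(100L, 50L, 100L), gene_id = "G1",
    transcript_ids = list("T1", "T2", "T1"), n_transcripts = 1L)
  introns
}

novel_row <- function(id, category, acceptor_ids, donor_ids = character(),
                      strand = "+") {
  tibble::tibble(junction_id = id, category = category,
                 resolved_strand = strand,
                 matched_donor_intron_ids = list(donor_ids),
                 matched_acceptor_intron_ids = list(acceptor_ids),
                 annotated_intron_ids = list(character()))
}

test_that("co-detection admits parents only when annotated in every novel sample", {
  introns <- pairing_fixture()
  novel <- novel_row("chr1:180-500:+", "novel_donor", "C")
  counts <- tibble::tibble(junction_id = "chr1:180-500:+",
                           sample_id = c("s1", "s2"), count = c(2L, 1L))
  annot_full <- tibble::tibble(intron_id = "C", sample_id = c("s1", "s2"),
                               count = 10L)
  got <- candidate_parents(novel, counts, annot_full)
  expect_equal(got$candidates[[1]], "C")
  # drop the annotated evidence in one of the junction's samples
  annot_partial <- annot_full[1, ]
  got2 <- candidate_parents(novel, counts, annot_partial)
  expect_length(got2$candidates[[1]], 0)
})

test_that("a shared acceptor with two co-detected introns yields both candidates", {
  introns <- pairing_fixture()
  novel <- novel_row("chr1:150-300:+", "novel_donor", c("A", "B"))
  counts <- tibble::tibble(junction_id = "chr1:150-300:+",
                           sample_id = "s1", count = 3L)
  annot <- tibble::tibble(intron_id = c("A", "B"), sample_id = "s1",
                          count = c(5L, 8L))
  got <- candidate_parents(novel, counts, annot)
  expect_setequal(got$candidates[[1]], c("A", "B"))
})

test_that("pair resolution emits unique pairs and audits ambiguity exactly", {
  introns <- pairing_fixture()
  junctions <- make_junctions("chr1:150-300:+",  # ambiguous (A and B)
                              "chr1:180-500:+",  # unique parent C
                              "chr1:120-500:+")  # unpairable (C missing in s2)
  novel <- dplyr::bind_rows(
    novel_row(junctions$junction_id[1], "novel_donor", c("A", "B")),
    novel_row(junctions$junction_id[2], "novel_donor", "C"),
    novel_row(junctions$junction_id[3], "novel_donor", "C"))
  counts <- tibble::tibble(
    junction_id = junctions$junction_id[c(1, 2, 3)],
    sample_id = c("s1", "s1", "s2"), count = 2L)
  annot <- tibble::tibble(intron_id = c("A", "B", "C"), sample_id = "s1",
                          count = 5L)
  res <- resolve_pairs(novel, junctions, counts, annot, introns)
  expect_equal(res$audit$n_paired, 1)
  expect_equal(res$audit$n_ambiguous, 1)
  expect_equal(res$audit$n_unpairable, 1)
  expect_equal(res$pairs$intron_id, "C")
  expect_equal(res$pairs$shared_site_pos, 500L)
  expect_equal(res$pairs$novel_site_pos, 180L)
  # A and B were candidates of an ambiguous junction and parent no pair
  expect_setequal(res$audit$dropped_intron_ids, c("A", "B"))
  res2 <- resolve_pairs(novel, junctions, counts, annot, introns,
                        drop_parenting_introns = FALSE)
  expect_length(res2$audit$dropped_intron_ids, 0)
})

test_that("the hierarchy inverts pairs one-to-N and rejects duplicate children", {
  pairs <- tibble::tibble(novel_junction_id = c("n1", "n2", "n3"),
                          intron_id = c("A", "A", "B"),
                          novel_type = "novel_donor",
                          shared_site_pos = 300L, novel_site_pos = 250L)
  h <- pairs_to_hierarchy(pairs)
  expect_setequal(h$novel_junction_ids[h$intron_id == "A"][[1]], c("n1", "n2"))
  expect_equal(h$novel_junction_ids[h$intron_id == "B"][[1]], "n3")
  # round trip reproduces the pair set
  back <- tidyr::unnest_longer(h, novel_junction_ids,
                               values_to = "novel_junction_id")
  expect_setequal(paste(back$intron_id, back$novel_junction_id),
                  paste(pairs$intron_id, pairs$novel_junction_id))
  expect_equal(nrow(pairs_to_hierarchy(pairs[0, ])), 0)
  expect_error(pairs_to_hierarchy(dplyr::bind_rows(pairs, pairs[1, ])),
               "duplicate")
})

test_that("adding parent evidence never shrinks a candidate set", {
  novel <- novel_row("chr1:150-300:+", "novel_donor", c("A", "B"))
  counts <- tibble::tibble(junction_id = "chr1:150-300:+",
                           sample_id = c("s1", "s2"), count = 1L)
  annot_small <- tibble::tibble(intron_id = "A",
                                sample_id = c("s1", "s2"), count = 1L)
  small <- candidate_parents(novel, counts, annot_small)$candidates[[1]]
  annot_big <- dplyr::bind_rows(
    annot_small, tibble::tibble(intron_id = "B", sample_id = c("s1", "s2"),
                                count = 1L))
  big <- candidate_parents(novel, counts, annot_big)$candidates[[1]]
  expect_true(all(small %in% big))
})
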