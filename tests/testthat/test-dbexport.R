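test_that("the database materialises master and per-tissue child tables", {
  build <- shared_build()
  db <- file.path(tempdir(), "unit.sqlite")
  unlink(db)
  build_intron_database(build, db)
  con <- DBI::dbConnect(RSQLite::SQLite(), db)
  on.exit(DBI::dbDisconnect(con))
  tabs <- DBI::dbListTables(con)
  expect_true(all(c("gene", "intron", "novel", "tissues", "metadata") %in% tabs))
  tissues <- DBI::dbGetQuery(con, "SELECT slug FROM tissues")$slug
  expect_length(tissues, 3)
  for (s in tissues) {
    expect_true(paste0(s, "_intron_stats") %in% tabs)
    expect_true(paste0(s, "_novel_stats") %in% tabs)
  }
  # 1:N cardinality: novel junctions are unique rows
  n <- DBI::dbGetQuery(con, paste(
    "SELECT COUNT(*) AS rows, COUNT(DISTINCT novel_junction_id) AS ids",
    "FROM novel"))
  expect_equal(n$rows, n$ids)
  expect_equal(n$rows, nrow(build$pairs))
  # refuses to clobber without force
  expect_error(build_intron_database(build, db), "force")
})

test_that("child-table rows round-trip the in-memory statistics bit for bit", {
  build <- shared_build()
  db <- file.path(tempdir(), "roundtrip.sqlite")
  build_intron_database(build, db, force = TRUE)
  con <- DBI::dbConnect(RSQLite::SQLite(), db)
  on.exit(DBI::dbDisconnect(con))
  for (t in unique(build$intron_stats$tissue)) {
    got <- read_db_table(con, paste0(tissue_slug(t), "_intron_stats"))
    want <- build$intron_stats |>
      dplyr::filter(tissue == t) |>
      dplyr::select(-tissue)
    expect_identical(as.data.frame(got), as.data.frame(want))
  }
})

test_that("rebuilds from identical inputs are row-identical", {
  build <- shared_build()
  d1 <- file.path(tempdir(), "db_a.sqlite")
  d2 <- file.path(tempdir(), "db_b.sqlite")
  build_intron_database(build, d1, force = TRUE)
  build_intron_database(build, d2, force = TRUE)
  c1 <- DBI::dbConnect(RSQLite::SQLite(), d1)
  c2 <- DBI::dbConnect(RSQLite::SQLite(), d2)
  on.exit({DBI::dbDisconnect(c1); DBI::dbDisconnect(c2)})
  for (t in DBI::dbListTables(c1)) {
    expect_identical(DBI::dbReadTable(c1, t), DBI::dbReadTable(c2, t))
  }
})

test_that("queries honour mode, tissue selection and conjunctive filters", {
  build <- shared_build()
  db <- file.path(tempdir(), "query.sqlite")
  cat <- build$catalogue
  clin <- flag_clinvar(cat$introns,
                       tibble::tibble(chrom = cat$introns$chrom[1],
                                      pos = cat$introns$start[1] + 5L))
  build_intron_database(build, db, intron_features = clin, force = TRUE)

  it <- cat$introns[1, ]
  got <- query_intron_db(db, "by_coordinates",
                         coordinates = sprintf("%s:%d-%d", it$chrom,
                                               it$start, it$end),
                         tissue = "tissue_01")
  expect_lte(nrow(got), 2)  # one row per matching intron in that tissue
  expect_true(all(got$start == it$start))

  one_gene <- query_intron_db(db, "by_gene", gene = it$gene_id)
  expect_true(all(one_gene$gene_id == it$gene_id))
  expect_setequal(unique(one_gene$tissue),
                  unique(build$intron_stats$tissue))

  lst <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(gene = c(it$gene_id, "G999")), lst)
  expect_message(by_list <- query_intron_db(db, "by_gene_list",
                                            gene_list = lst),
                 "not found")
  expect_setequal(unique(by_list$gene_id), it$gene_id)

  mane <- query_intron_db(db, "by_gene", gene = it$gene_id, mane_only = TRUE)
  expect_true(all(mane$in_mane == 1))
  clin_only <- query_intron_db(db, "by_coordinates",
                               coordinates = sprintf("%s:%d-%d", it$chrom,
                                                     it$start, it$end),
                               clinvar_only = TRUE)
  expect_true(all(clin_only$clinvar == 1))

  expect_error(query_intron_db(db, "by_coordinates",
                               coordinates = "chr1;bad"), "malformed")
  expect_message(empty <- query_intron_db(db, "by_gene", gene = "NOPE"),
                 "not found")
  expect_equal(nrow(empty), 0)
})

test_that("the support filter restricts query hits to high-support parents", {
  sim <- shared_sim()
  build <- shared_build()
  db <- file.path(tempdir(), "support.sqlite")
  build_intron_database(build, db, force = TRUE)
  hs <- sim$truth$high_support
  got <- query_intron_db(db, "by_gene",
                         gene = build$pairs$intron_id[
                           build$pairs$novel_junction_id == hs$junction_id[1]] |>
                           (\(x) build$catalogue$introns$gene_id[
                             build$catalogue$introns$intron_id == x])(),
                         tissue = hs$tissue[1],
                         support_min_pct = hs$target_pct[1])
  parent <- build$pairs$intron_id[build$pairs$novel_junction_id ==
                                    hs$junction_id[1]]
  expect_true(parent %in% got$intron_id)
})

test_that("table export writes faithful flat files", {
  build <- shared_build()
  db <- file.path(tempdir(), "export.sqlite")
  build_intron_database(build, db, force = TRUE)
  dir <- file.path(tempdir(), "exports")
  paths <- export_db_tables(db, c("intron", "novel"), dir = dir)
  back <- readr::read_csv(paths[["intron"]], show_col_types = FALSE)
  con <- DBI::dbConnect(RSQLite::SQLite(), db)
  on.exit(DBI::dbDisconnect(con))
  expect_equal(nrow(back),
               DBI::dbGetQuery(con, "SELECT COUNT(*) n FROM intron")$n)
  expect_error(export_db_tables(db, "no_such_table"), "available")
})
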