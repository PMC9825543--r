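#' Sanitise a tissue name into a table-name slug
#'
#' @param tissue Character vector of tissue display names.
#' @return Lower-case slug usable in SQL table names.
#' @export
tissue_slug <- function(tissue) {
  slug <- tolower(gsub("[^A-Za-z0-9]+", "_", tissue))
  gsub("^_+|_+$", "", slug)
}

#' Materialise the hierarchical intron database
#'
#' Writes an SQLite file with three master tables — `gene`, `intron` and
#' `novel` (each novel junction referencing exactly one parent intron) —
#' and two child tables per tissue, `<slug>_intron_stats` and
#' `<slug>_novel_stats`, plus a `tissues` lookup table and a `metadata`
#' provenance table (pipeline parameters and package version). Lookup keys
#' (coordinates, `gene_id`, `intron_id`) are indexed, and foreign keys are
#' validated after the load.
#'
#' @param build A `splice_build` from [run_splice_pipeline()].
#' @param out_path Output SQLite file path.
#' @param novel_features Optional extra columns for the `novel` master table
#'   (tibble keyed by `novel_junction_id`, e.g. splice-site scores).
#' @param intron_features Optional extra columns for the `intron` master
#'   table (tibble keyed by `intron_id`, e.g. `clinvar`, window score
#'   means).
#' @param force Overwrite an existing file (default `FALSE`: refuse).
#' @return `out_path`, invisibly.
#' @export
build_intron_database <- function(build, out_path, novel_features = NULL,
                                  intron_features = NULL, force = FALSE) {
  if (file.exists(out_path) && !force) {
    abort(sprintf("%s exists; use force = TRUE to overwrite", out_path))
  }
  if (file.exists(out_path)) unlink(out_path)

  introns <- build$catalogue$introns %>%
    mutate(transcript_ids = purrr::map_chr(.data$transcript_ids,
                                           paste, collapse = ","))
  dropped <- build$pairing_audit$dropped_intron_ids
  introns <- filter(introns, !.data$intron_id %in% dropped)
  if (!is.null(intron_features)) {
    introns <- left_join(introns, as_tibble(intron_features),
                         by = "intron_id")
  }
  genes <- build$catalogue$genes %>%
    filter(.data$gene_id %in% introns$gene_id)

  novel <- build$pairs %>%
    left_join(distance_and_frameshift(build$pairs, build$catalogue$introns),
              by = c("novel_junction_id", "intron_id")) %>%
    left_join(select(build$junctions, "junction_id", "chrom", "strand",
                     "start", "end", "implied_length"),
              by = c(novel_junction_id = "junction_id"))
  if (!is.null(novel_features)) {
    novel <- left_join(novel, as_tibble(novel_features),
                       by = "novel_junction_id")
  }
  bad_fk <- setdiff(novel$intron_id, introns$intron_id)
  if (length(bad_fk) > 0) {
    abort(sprintf("foreign-key violation: novel junction references unknown intron %s",
                  bad_fk[1]))
  }

  con <- DBI::dbConnect(RSQLite::SQLite(), out_path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  # SQLite has no logical storage class, so R column types are recorded in
  # a schema_types table and restored by read_db_table()
  types <- list()
  write_table <- function(name, df) {
    DBI::dbWriteTable(con, name, df)
    types[[length(types) + 1]] <<- tibble(
      table_name = name, column = names(df),
      r_class = vapply(df, function(x) class(x)[1], character(1)))
  }
  write_table("gene", genes)
  write_table("intron", introns)
  write_table("novel", novel)

  tissues <- sort(unique(c(build$intron_stats$tissue,
                           build$novel_stats$tissue)))
  write_table("tissues",
              tibble(slug = tissue_slug(tissues), tissue = tissues))
  for (t in tissues) {
    slug <- tissue_slug(t)
    write_table(paste0(slug, "_intron_stats"),
                filter(build$intron_stats, .data$tissue == t) %>%
                  select(-"tissue"))
    write_table(paste0(slug, "_novel_stats"),
                filter(build$novel_stats, .data$tissue == t) %>%
                  select(-"tissue"))
  }
  DBI::dbWriteTable(con, "schema_types", bind_rows(types))

  DBI::dbWriteTable(con, "metadata", tibble(
    key = c("pipeline_version", names(build$params)),
    value = c(as.character(utils::packageVersion("intronaut")),
              vapply(build$params, function(x) paste(deparse(x), collapse = ""),
                     character(1)))))

  DBI::dbExecute(con, "CREATE INDEX idx_intron_coord ON intron(chrom, start, end, strand)")
  DBI::dbExecute(con, "CREATE INDEX idx_intron_gene ON intron(gene_id)")
  DBI::dbExecute(con, "CREATE INDEX idx_novel_intron ON novel(intron_id)")
  DBI::dbExecute(con, "CREATE INDEX idx_gene_symbol ON gene(symbol)")

  check_referential_integrity(con)
  invisible(out_path)
}

#' Read a database table with original column types restored
#'
#' SQLite stores logicals as integers; this reader consults the database's
#' `schema_types` table to give back the tibble exactly as it was written.
#'
#' @param db Database path or an open DBI connection.
#' @param name Table name.
#' @return Tibble.
#' @export
read_db_table <- function(db, name) {
  con <- if (is.character(db)) {
    DBI::dbConnect(RSQLite::SQLite(), db)
  } else {
    db
  }
  if (is.character(db)) on.exit(DBI::dbDisconnect(con), add = TRUE)
  out <- as_tibble(DBI::dbReadTable(con, name))
  if ("schema_types" %in% DBI::dbListTables(con)) {
    sch <- DBI::dbReadTable(con, "schema_types")
    logi <- sch$column[sch$table_name == name & sch$r_class == "logical"]
    for (col in intersect(logi, names(out))) {
      out[[col]] <- as.logical(out[[col]])
    }
  }
  out
}

# full foreign-key scan over the loaded database
check_referential_integrity <- function(con) {
  orphan_novel <- DBI::dbGetQuery(con, paste(
    "SELECT COUNT(*) AS n FROM novel",
    "WHERE intron_id NOT IN (SELECT intron_id FROM intron)"))$n
  orphan_intron <- DBI::dbGetQuery(con, paste(
    "SELECT COUNT(*) AS n FROM intron",
    "WHERE gene_id NOT IN (SELECT gene_id FROM gene)"))$n
  bad_child <- 0L
  slugs <- DBI::dbGetQuery(con, "SELECT slug FROM tissues")$slug
  for (s in slugs) {
    bad_child <- bad_child + DBI::dbGetQuery(con, sprintf(paste(
      "SELECT COUNT(*) AS n FROM %s_intron_stats",
      "WHERE intron_id NOT IN (SELECT intron_id FROM intron)"), s))$n
    bad_child <- bad_child + DBI::dbGetQuery(con, sprintf(paste(
      "SELECT COUNT(*) AS n FROM %s_novel_stats",
      "WHERE novel_junction_id NOT IN (SELECT novel_junction_id FROM novel)"),
      s))$n
  }
  if (orphan_novel + orphan_intron + bad_child > 0) {
    abort(sprintf("referential integrity violated (%d novel, %d intron, %d child rows)",
                  orphan_novel, orphan_intron, bad_child))
  }
  invisible(TRUE)
}

#' Query annotated introns from the database
#'
#' Implements the three search modes — by exact intron coordinates, by gene
#' (id or symbol), or by a gene list file (single-column CSV/TSV with a
#' header, one gene symbol or id per row) — joined with the per-tissue
#' intron statistics. Filters are conjunctive: `support_min_pct` keeps
#' introns with at least one associated novel junction used in at least
#' that percentage of the tissue's samples; `clinvar_only` and `mane_only`
#' require the corresponding intron flags.
#'
#' @param db_path SQLite database from [build_intron_database()].
#' @param mode `"by_coordinates"`, `"by_gene"` or `"by_gene_list"`.
#' @param coordinates For `by_coordinates`: string `"chrom:start-end"` or
#'   `"chrom:start-end:strand"`.
#' @param gene For `by_gene`: a gene id or symbol.
#' @param gene_list For `by_gene_list`: path to the gene list file.
#' @param tissue One tissue display name, several, or `NULL` for all.
#' @param support_min_pct Optional minimum novel-junction support
#'   percentage.
#' @param clinvar_only,mane_only Logical flags.
#' @return Tibble of intron rows joined with the selected tissues' stats
#'   (one row per intron and tissue; empty with a message for unknown
#'   genes).
#' @export
query_intron_db <- function(db_path,
                            mode = c("by_coordinates", "by_gene",
                                     "by_gene_list"),
                            coordinates = NULL, gene = NULL,
                            gene_list = NULL, tissue = NULL,
                            support_min_pct = NULL,
                            clinvar_only = FALSE, mane_only = FALSE) {
  mode <- match.arg(mode)
  con <- DBI::dbConnect(RSQLite::SQLite(), db_path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  intron <- read_db_table(con, "intron")
  genes_tab <- read_db_table(con, "gene")

  sel <- switch(mode,
    by_coordinates = {
      if (is.null(coordinates)) abort("by_coordinates mode needs coordinates")
      m <- stringr::str_match(coordinates,
                              "^([^:]+):(\\d+)-(\\d+)(?::([+-]))?$")
      if (is.na(m[1, 1])) {
        abort(sprintf("malformed coordinate string: %s", coordinates))
      }
      hit <- intron$chrom == m[1, 2] &
        intron$start == as.integer(m[1, 3]) &
        intron$end == as.integer(m[1, 4])
      if (!is.na(m[1, 5])) hit <- hit & intron$strand == m[1, 5]
      intron[hit, , drop = FALSE]
    },
    by_gene = {
      if (is.null(gene)) abort("by_gene mode needs gene")
      ids <- genes_tab$gene_id[genes_tab$gene_id == gene |
                                 (!is.na(genes_tab$symbol) &
                                    genes_tab$symbol == gene)]
      if (length(ids) == 0) {
        inform(sprintf("gene %s not found in database", gene))
      }
      filter(intron, .data$gene_id %in% ids)
    },
    by_gene_list = {
      if (is.null(gene_list)) abort("by_gene_list mode needs gene_list")
      lst <- readr::read_csv(gene_list, col_types = readr::cols(.default = "c"))
      wanted <- lst[[1]]
      ids <- genes_tab$gene_id[genes_tab$gene_id %in% wanted |
                                 genes_tab$symbol %in% wanted]
      miss <- setdiff(wanted, c(genes_tab$gene_id, genes_tab$symbol))
      if (length(miss) > 0) {
        inform(sprintf("gene(s) not found: %s", paste(miss, collapse = ", ")))
      }
      filter(intron, .data$gene_id %in% ids)
    })

  if (clinvar_only) {
    if (!"clinvar" %in% names(sel)) abort("database has no clinvar flag")
    sel <- filter(sel, .data$clinvar)
  }
  if (mane_only) sel <- filter(sel, .data$in_mane)

  tissues_tab <- read_db_table(con, "tissues")
  if (!is.null(tissue)) {
    tissues_tab <- filter(tissues_tab, .data$tissue %in% !!tissue)
  }
  stats <- purrr::map(seq_len(nrow(tissues_tab)), function(i) {
    read_db_table(con, paste0(tissues_tab$slug[i], "_intron_stats")) %>%
      mutate(tissue = tissues_tab$tissue[i])
  }) %>% bind_rows()
  out <- inner_join(sel, stats, by = "intron_id")

  if (!is.null(support_min_pct)) {
    if (support_min_pct < 0 || support_min_pct > 100) {
      abort("support_min_pct must lie in [0, 100]")
    }
    nov <- purrr::map(seq_len(nrow(tissues_tab)), function(i) {
      read_db_table(con, paste0(tissues_tab$slug[i], "_novel_stats")) %>%
        mutate(tissue = tissues_tab$tissue[i])
    }) %>% bind_rows()
    novel_tab <- read_db_table(con, "novel")
    supported <- nov %>%
      filter(.data$pct_samples_used >= support_min_pct) %>%
      distinct(.data$novel_junction_id, .data$tissue) %>%
      inner_join(select(novel_tab, "novel_junction_id", "intron_id"),
                 by = "novel_junction_id") %>%
      distinct(.data$intron_id, .data$tissue)
    out <- semi_join(out, supported, by = c("intron_id", "tissue"))
  }
  as_tibble(out)
}

#' Export database tables to flat files
#'
#' Writes the requested tables column-faithfully as CSV or TSV (full
#' numeric precision, `.` decimal separator).
#'
#' @param db_path SQLite database path.
#' @param tables Character vector of table names (default: all).
#' @param dir Output directory.
#' @param format `"csv"` or `"tsv"`.
#' @return Named character vector of written file paths.
#' @export
export_db_tables <- function(db_path, tables = NULL, dir = ".",
                             format = c("csv", "tsv")) {
  format <- match.arg(format)
  con <- DBI::dbConnect(RSQLite::SQLite(), db_path)
  on.exit(DBI::dbDisconnect(con), add = TRUE)
  avail <- DBI::dbListTables(con)
  tables <- tables %||% avail
  unknown <- setdiff(tables, avail)
  if (length(unknown) > 0) {
    abort(sprintf("unknown table(s): %s; available: %s",
                  paste(unknown, collapse = ", "),
                  paste(avail, collapse = ", ")))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writer <- if (format == "csv") readr::write_csv else readr::write_tsv
  paths <- vapply(tables, function(t) {
    p <- file.path(dir, paste0(t, ".", format))
    writer(read_db_table(con, t), p)
    p
  }, character(1))
  paths
}
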