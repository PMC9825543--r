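#' Configuration for the synthetic splicing dataset
#'
#' Defines the generative model and the planted test cases of the
#' self-contained synthetic dataset. Defaults describe a small but fully
#' featured study: 50 genes over a toy genome, 3 tissues of 10 samples each
#' (plus 2 excluded samples), annotated read depth of mean 100 reads per
#' intron and sample, and per-intron mis-splicing rates drawn from a
#' zero-inflated Beta mixture (point mass at 0 with probability
#' `zero_missplice_prob`, otherwise `Beta(beta_shape1, beta_shape2)`).
#'
#' Planted cases cover every quality-control and classification branch:
#' junctions failing exactly one QC filter (`short`, `scaffold`,
#' `blacklist`), junctions of the discarded classification categories
#' (`combo`, `exon_skip`, `gene_ambiguous`, `unannotated`), pairing
#' stress cases (`ambiguous` — a novel site whose shared annotated splice
#' site belongs to two co-detected introns; `unpairable` — a novel junction
#' observed in a sample where its only compatible intron has no annotated
#' read), and a `high_support` junction present in a target percentage of
#' one tissue's samples.
#'
#' @param n_genes Total genes (regular plus dedicated plant genes).
#' @param n_tissues,samples_per_tissue,n_excluded Sample layout.
#' @param transcripts_per_gene,exons_per_transcript Integer ranges
#'   `c(min, max)`.
#' @param exon_length,intron_length Length ranges in bp.
#' @param annotated_depth_lambda Mean annotated reads per intron per sample.
#' @param depth_dispersion `NULL` for Poisson depth, or a negative-binomial
#'   size parameter for overdispersed depth.
#' @param zero_missplice_prob,beta_shape1,beta_shape2 Mis-splicing rate
#'   mixture.
#' @param novel_offset_range Absolute genomic offset range (bp) of novel
#'   splice sites from their annotated site.
#' @param fixed_p_d,fixed_p_a Optional numeric vectors of fixed per-intron
#'   mis-splicing rates, recycled over the regular introns in catalogue
#'   order; when given they replace the mixture draw (used for parameter-
#'   recovery studies).
#' @param planted Named list of planted-case counts (see Details).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_genes = 50, n_tissues = 3,
                              samples_per_tissue = 10, n_excluded = 2,
                              transcripts_per_gene = c(1, 3),
                              exons_per_transcript = c(3, 6),
                              exon_length = c(80, 200),
                              intron_length = c(80, 400),
                              annotated_depth_lambda = 100,
                              depth_dispersion = NULL,
                              zero_missplice_prob = 0.3,
                              beta_shape1 = 1.5, beta_shape2 = 30,
                              novel_offset_range = c(3, 30),
                              fixed_p_d = NULL, fixed_p_a = NULL,
                              planted = list()) {
  planted <- utils::modifyList(list(
    short = 7, scaffold = 5, blacklist = 6,
    combo = 1, exon_skip = 1, gene_ambiguous = 2, unannotated = 3,
    ambiguous = 10, unpairable = 5,
    high_support = list(n = 1, tissue = 1, pct = 90)), planted)
  cfg <- list(n_genes = n_genes, n_tissues = n_tissues,
              samples_per_tissue = samples_per_tissue,
              n_excluded = n_excluded,
              transcripts_per_gene = transcripts_per_gene,
              exons_per_transcript = exons_per_transcript,
              exon_length = exon_length, intron_length = intron_length,
              annotated_depth_lambda = annotated_depth_lambda,
              depth_dispersion = depth_dispersion,
              zero_missplice_prob = zero_missplice_prob,
              beta_shape1 = beta_shape1, beta_shape2 = beta_shape2,
              novel_offset_range = novel_offset_range,
              fixed_p_d = fixed_p_d, fixed_p_a = fixed_p_a,
              planted = planted)
  if (!is.null(fixed_p_d) && any(fixed_p_d < 0 | fixed_p_d > 1)) {
    abort("fixed_p_d must lie in [0, 1]")
  }
  if (!is.null(fixed_p_a) && any(fixed_p_a < 0 | fixed_p_a > 1)) {
    abort("fixed_p_a must lie in [0, 1]")
  }
  n_dedicated <- planted$ambiguous + planted$unpairable +
    planted$high_support$n + planted$combo + planted$exon_skip
  if (n_genes - n_dedicated < max(4, 2 * (planted$gene_ambiguous > 0))) {
    abort("n_genes too small for the requested planted cases")
  }
  if (zero_missplice_prob < 0 || zero_missplice_prob > 1) {
    abort("zero_missplice_prob must lie in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a self-contained splicing dataset with ground truth
#'
#' Generates, under a fixed seed, a toy genome (FASTA, with GT/AG planted at
#' every annotated splice site), an Ensembl-dialect annotation (GTF), sample
#' metadata, per-sample STAR `SJ.out.tab` junction tables, a blacklist BED,
#' conservation/constraint score-track TSVs, join tables (synthetic ClinVar-
#' style variants, spliceosome classes, TPM) and a ground-truth manifest.
#'
#' The generative model: per intron and sample, total splicing events
#' `T ~ Poisson(lambda)` (or negative binomial when overdispersed); each
#' event is a donor mis-splice, an acceptor mis-splice, or an accurate
#' splice with probabilities chosen so that the pooled mis-splicing ratios
#' converge to the intron's true rates `p_D`, `p_A`. Novel reads land on
#' one novel donor and/or acceptor site per intron, at a fixed genomic
#' offset that avoids every annotated splice site.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; identical `(config, seed)` give byte-identical
#'   outputs.
#' @param out_dir Output directory (created if needed).
#' @return List with `dir`, `paths` (named file paths), `truth` (the
#'   ground-truth manifest) and `tables` (the in-memory generator tables).
#' @export
simulate_splicing_dataset <- function(config = simulation_config(), seed = 1,
                                      out_dir = tempfile("simdata")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "junctions"), showWarnings = FALSE)

  samples <- sim_samples(config)
  layout <- sim_gene_layout(config)
  ann <- sim_annotation(config, layout)
  rates <- sim_missplice_rates(config, ann$introns)
  novel <- sim_novel_sites(config, ann$introns, rates)
  cm <- sim_counts(config, samples, ann$introns, rates, novel)
  plants <- sim_plants(config, samples, ann, layout, cm)
  long <- bind_rows(plants$base_long, plants$long)

  truth <- sim_truth(config, samples, ann, rates, novel, cm, plants, long)
  paths <- sim_write_outputs(config, out_dir, samples, ann, layout, long,
                             plants, truth)
  list(dir = out_dir, paths = paths, truth = truth,
       tables = list(samples = samples, genes = ann$genes,
                     transcripts = ann$transcripts, exons = ann$exons,
                     introns = ann$introns, counts = long))
}

# ---- sample layout -------------------------------------------------------

sim_samples <- function(config) {
  tissues <- sprintf("tissue_%02d", seq_len(config$n_tissues))
  active <- purrr::map(seq_len(config$n_tissues), function(t) {
    tibble(sample_id = sprintf("t%02d_s%02d", t,
                               seq_len(config$samples_per_tissue)),
           tissue = tissues[t], excluded = FALSE)
  }) %>% bind_rows()
  excl <- tibble(sample_id = sprintf("excl_%02d", seq_len(config$n_excluded)),
                 tissue = tissues[1],
                 excluded = TRUE)
  bind_rows(active, excl)
}

# ---- gene layout and annotation -----------------------------------------

sim_gene_layout <- function(config) {
  p <- config$planted
  n_ded <- p$ambiguous + p$unpairable + p$high_support$n + p$combo + p$exon_skip
  roles <- c(rep("regular", config$n_genes - n_ded),
             rep("ambiguous", p$ambiguous),
             rep("unpairable", p$unpairable),
             rep("high_support", p$high_support$n),
             rep("combo", p$combo),
             rep("exon_skip", p$exon_skip))
  genes_per_chrom <- 10L
  tibble(gene_idx = seq_len(config$n_genes),
         role = roles,
         chrom = paste0("chr", ((seq_len(config$n_genes) - 1) %/% genes_per_chrom) + 1L),
         strand = rep(c("+", "+", "-", "-"),
                      length.out = config$n_genes))
}

sim_annotation <- function(config, layout) {
  exon_rng <- config$exons_per_transcript
  genes <- list(); transcripts <- list(); exons <- list()
  cursor <- list()
  for (i in seq_len(nrow(layout))) {
    chrom <- layout$chrom[i]; strand <- layout$strand[i]
    role <- layout$role[i]
    gid <- sprintf("G%03d", i)
    start <- (cursor[[chrom]] %||% 10000L) + 5000L
    n_ex <- sample(seq(exon_rng[1], exon_rng[2]), 1)
    if (role %in% c("exon_skip", "combo", "ambiguous")) n_ex <- max(n_ex, 3L)
    ex_len <- sample(seq(config$exon_length[1], config$exon_length[2]),
                     n_ex, replace = TRUE)
    in_len <- sample(seq(config$intron_length[1], config$intron_length[2]),
                     n_ex - 1, replace = TRUE)
    ex_start <- start + cumsum(c(0L, head(ex_len, -1) + in_len))
    ex_end <- ex_start + ex_len - 1L
    gene_end <- ex_end[n_ex]
    cursor[[chrom]] <- gene_end
    biotype <- if (runif(1) < 0.8) "protein_coding" else "lncRNA"
    genes[[i]] <- tibble(gene_id = gid, symbol = sprintf("SYM%03d", i),
                         chrom = chrom, strand = strand,
                         start = start, end = gene_end, biotype = biotype,
                         role = role)
    tx_windows <- sim_transcript_windows(config, role, n_ex)
    for (k in seq_along(tx_windows)) {
      tid <- sprintf("%s.T%d", gid, k)
      w <- tx_windows[[k]]
      es <- ex_start[w$idx]; ee <- ex_end[w$idx]
      # plant-specific boundary shifts (alternative donor/acceptor variants)
      if (!is.null(w$shift)) {
        es <- es + w$shift$start_shift
        ee <- ee + w$shift$end_shift
      }
      tsl <- sample(c(1:5, NA), 1)
      mane <- (k == 1 && biotype == "protein_coding")
      transcripts[[length(transcripts) + 1]] <-
        tibble(transcript_id = tid, gene_id = gid, biotype = biotype,
               tsl = tsl, is_mane_select = mane)
      exons[[length(exons) + 1]] <-
        tibble(transcript_id = tid, gene_id = gid, chrom = chrom,
               strand = strand, start = es, end = ee)
    }
  }
  genes <- bind_rows(genes)
  transcripts <- bind_rows(transcripts)
  exons <- bind_rows(exons) %>%
    arrange(.data$transcript_id, .data$start) %>%
    group_by(.data$transcript_id) %>%
    mutate(exon_rank = row_number(), n_exons = n()) %>%
    ungroup()
  introns <- derive_introns(exons) %>%
    left_join(select(genes, "gene_id", "role"), by = "gene_id")
  list(genes = genes, transcripts = transcripts, exons = exons,
       introns = introns)
}

# transcript structures per role: index windows into the gene's exon list,
# with optional boundary shifts for the alternative-site plant genes
sim_transcript_windows <- function(config, role, n_ex) {
  all_idx <- seq_len(n_ex)
  zero <- list(start_shift = rep(0L, n_ex), end_shift = rep(0L, n_ex))
  if (role == "ambiguous") {
    # alternative donor: second transcript extends exon 1 by 12 bp, so two
    # introns share one acceptor while their donors differ
    shift2 <- zero; shift2$end_shift[1] <- 12L
    return(list(list(idx = all_idx, shift = zero),
                list(idx = all_idx, shift = shift2)))
  }
  if (role == "combo") {
    # alternative donor AND acceptor at intron 1: a junction combining the
    # first transcript's donor with the second's acceptor is a novel combo
    shift2 <- zero; shift2$end_shift[1] <- 9L; shift2$start_shift[2] <- 9L
    return(list(list(idx = all_idx, shift = zero),
                list(idx = all_idx, shift = shift2)))
  }
  if (role %in% c("unpairable", "high_support", "exon_skip")) {
    return(list(list(idx = all_idx, shift = zero)))
  }
  # regular genes: up to three truncation isoforms (consecutive exon
  # windows), which share introns wholesale and never create partial sites
  n_tx <- sample(seq(config$transcripts_per_gene[1],
                     config$transcripts_per_gene[2]), 1)
  out <- list(list(idx = all_idx, shift = zero))
  if (n_tx >= 2 && n_ex >= 3) {
    z <- list(start_shift = rep(0L, n_ex - 1), end_shift = rep(0L, n_ex - 1))
    out <- c(out, list(list(idx = all_idx[-n_ex], shift = z)))
  }
  if (n_tx >= 3 && n_ex >= 3) {
    z <- list(start_shift = rep(0L, n_ex - 1), end_shift = rep(0L, n_ex - 1))
    out <- c(out, list(list(idx = all_idx[-1], shift = z)))
  }
  out
}

# ---- mis-splicing model --------------------------------------------------

sim_missplice_rates <- function(config, introns) {
  n <- nrow(introns)
  regular <- introns$role == "regular"
  draw <- function() {
    if (runif(1) < config$zero_missplice_prob) 0
    else rbeta(1, config$beta_shape1, config$beta_shape2)
  }
  n_reg <- sum(regular)
  pd_reg <- if (is.null(config$fixed_p_d)) {
    vapply(seq_len(n_reg), function(i) draw(), 0)
  } else {
    rep_len(config$fixed_p_d, n_reg)
  }
  pa_reg <- if (is.null(config$fixed_p_a)) {
    vapply(seq_len(n_reg), function(i) draw(), 0)
  } else {
    rep_len(config$fixed_p_a, n_reg)
  }
  p_d <- p_a <- rep(0, n)
  p_d[regular] <- pd_reg
  p_a[regular] <- pa_reg
  tibble(intron_id = introns$intron_id, p_d = p_d, p_a = p_a)
}

# choose one novel donor and/or acceptor site per mis-spliced intron, at a
# genomic offset that collides with no annotated splice site
sim_novel_sites <- function(config, introns, rates) {
  site_pool <- unique(c(paste(introns$chrom, introns$donor_pos),
                        paste(introns$chrom, introns$acceptor_pos)))
  rng <- config$novel_offset_range
  pick_offset <- function(chrom, anchor, span_ok) {
    cand <- sample(c(-(rng[1]:rng[2]), rng[1]:rng[2]))
    for (o in cand) {
      pos <- anchor + o
      if (paste(chrom, pos) %in% site_pool) next
      if (!span_ok(pos)) next
      return(pos)
    }
    NA_integer_
  }
  out <- list()
  for (i in seq_len(nrow(introns))) {
    r <- rates[rates$intron_id == introns$intron_id[i], ]
    if (r$p_d == 0 && r$p_a == 0) next
    it <- introns[i, ]
    if (r$p_d > 0) {
      pos <- pick_offset(it$chrom, it$donor_pos, function(p) {
        s <- if (it$strand == "-") it$start else p
        e <- if (it$strand == "-") p else it$end
        s < e && (e - s + 1) >= 25
      })
      if (!is.na(pos)) {
        s <- if (it$strand == "-") it$start else pos
        e <- if (it$strand == "-") pos else it$end
        out[[length(out) + 1]] <- tibble(
          intron_id = it$intron_id, side = "donor", chrom = it$chrom,
          strand = it$strand, start = s, end = e, novel_pos = pos)
      }
    }
    if (r$p_a > 0) {
      pos <- pick_offset(it$chrom, it$acceptor_pos, function(p) {
        s <- if (it$strand == "-") p else it$start
        e <- if (it$strand == "-") it$end else p
        s < e && (e - s + 1) >= 25
      })
      if (!is.na(pos)) {
        s <- if (it$strand == "-") pos else it$start
        e <- if (it$strand == "-") it$end else pos
        out[[length(out) + 1]] <- tibble(
          intron_id = it$intron_id, side = "acceptor", chrom = it$chrom,
          strand = it$strand, start = s, end = e, novel_pos = pos)
      }
    }
  }
  sites <- bind_rows(out)
  if (nrow(sites) > 0) {
    sites$junction_id <- junction_coord_id(sites$chrom, sites$start,
                                           sites$end, sites$strand)
  }
  sites
}

# per-event probabilities making the pooled ratio-of-sums converge to the
# target rates despite the shared annotated denominator
sim_event_probs <- function(p_d, p_a) {
  den <- 1 - p_d * p_a
  a <- p_d * (1 - p_a) / den
  b <- p_a * (1 - p_d) / den
  c(a, b, 1 - a - b)
}

sim_counts <- function(config, samples, introns, rates, novel) {
  active <- samples$sample_id[!samples$excluded]
  excl <- samples$sample_id[samples$excluded]
  lam <- config$annotated_depth_lambda
  draw_depth <- function(n) {
    if (is.null(config$depth_dispersion)) rpois(n, lam)
    else stats::rnbinom(n, size = config$depth_dispersion, mu = lam)
  }
  rows <- list()
  novel_by_intron <- if (nrow(novel) > 0) split(novel, novel$intron_id) else list()
  for (i in seq_len(nrow(introns))) {
    it <- introns[i, ]
    r <- rates[rates$intron_id == it$intron_id, ]
    pr <- sim_event_probs(r$p_d, r$p_a)
    total <- draw_depth(length(active))
    split3 <- vapply(total, function(t) {
      if (t == 0) c(0L, 0L, 0L) else as.integer(rmultinom(1, t, pr))
    }, integer(3))
    ns <- novel_by_intron[[it$intron_id]]
    nd <- if (!is.null(ns)) ns[ns$side == "donor", ] else NULL
    na_ <- if (!is.null(ns)) ns[ns$side == "acceptor", ] else NULL
    rows[[length(rows) + 1]] <- tibble(
      chrom = it$chrom, start = it$start, end = it$end, strand = it$strand,
      sample_id = active, count = split3[3, ], kind = "annotated",
      intron_id = it$intron_id)
    if (!is.null(nd) && nrow(nd) == 1) {
      rows[[length(rows) + 1]] <- tibble(
        chrom = nd$chrom, start = nd$start, end = nd$end, strand = nd$strand,
        sample_id = active, count = split3[1, ], kind = "novel_donor",
        intron_id = it$intron_id)
    }
    if (!is.null(na_) && nrow(na_) == 1) {
      rows[[length(rows) + 1]] <- tibble(
        chrom = na_$chrom, start = na_$start, end = na_$end,
        strand = na_$strand, sample_id = active, count = split3[2, ],
        kind = "novel_acceptor", intron_id = it$intron_id)
    }
    if (length(excl) > 0) {
      rows[[length(rows) + 1]] <- tibble(
        chrom = it$chrom, start = it$start, end = it$end, strand = it$strand,
        sample_id = excl, count = draw_depth(length(excl)),
        kind = "annotated", intron_id = it$intron_id)
    }
  }
  long <- bind_rows(rows) %>% filter(.data$count > 0)
  long$junction_id <- junction_coord_id(long$chrom, long$start, long$end,
                                        long$strand)
  list(long = long)
}

# ---- planted cases -------------------------------------------------------

sim_plants <- function(config, samples, ann, layout, cm) {
  p <- config$planted
  active <- samples$sample_id[!samples$excluded]
  introns <- ann$introns
  exons <- ann$exons
  genes <- ann$genes
  long <- cm$long
  rows <- list()
  reg <- list()
  add <- function(registry, chrom, start, end, strand, sample_ids, counts,
                  strand_code_zero = FALSE) {
    jid <- junction_coord_id(chrom, start, end,
                             if (strand_code_zero) "*" else strand)
    rows[[length(rows) + 1]] <<- tibble(
      chrom = chrom, start = start, end = end,
      strand = if (strand_code_zero) "*" else strand,
      sample_id = sample_ids, count = counts, kind = registry,
      intron_id = NA_character_, junction_id = jid)
    reg[[registry]] <<- c(reg[[registry]], jid)
    jid
  }

  chrom_end <- long %>% group_by(.data$chrom) %>%
    summarise(mx = max(.data$end), .groups = "drop")
  far <- setNames(chrom_end$mx + 5000L, chrom_end$chrom)

  # QC plants: each fails exactly one filter
  pos <- far[["chr1"]]
  for (k in seq_len(p$short)) {
    len <- sample(10:24, 1)
    add("qc_short", "chr1", pos, pos + len - 1L, "+",
        sample(active, 1), sample(2:6, 1))
    pos <- pos + 300L
  }
  for (k in seq_len(p$scaffold)) {
    add("qc_scaffold", "chrUn_KI270302v1", 1000L + k * 500L,
        1000L + k * 500L + 120L, "+", sample(active, 1), sample(2:6, 1))
  }
  bl_anchor <- if ("chr2" %in% names(far)) far[["chr2"]] else 50000L
  blacklist <- tibble(chrom = "chr2",
                      start = bl_anchor + c(0L, 3000L),
                      end = bl_anchor + c(999L, 3999L))
  for (k in seq_len(p$blacklist)) {
    s <- blacklist$start[1 + (k %% 2)] + 100L + k * 50L
    add("qc_blacklist", "chr2", s, s + 150L, "+",
        sample(active, 1), sample(2:6, 1))
  }

  # classification plants (discarded categories)
  combo_gene <- genes$gene_id[genes$role == "combo"]
  if (p$combo > 0 && length(combo_gene) > 0) {
    gi <- introns[introns$gene_id == combo_gene[1], ]
    gi <- gi[order(gi$start), ]
    # the two intron-1 variants are offset by 9 bp at both boundaries;
    # combining the left start with the right end matches two annotated
    # sites of one gene without reproducing an annotated intron
    a <- gi[1, ]; b <- gi[2, ]
    add("class_combo", a$chrom, a$start, b$end, a$strand,
        sample(active, 1), 3L)
  }
  skip_gene <- genes$gene_id[genes$role == "exon_skip"]
  if (p$exon_skip > 0 && length(skip_gene) > 0) {
    gi <- introns[introns$gene_id == skip_gene[1], ]
    gi <- gi[order(gi$start), ]
    add("class_exon_skip", gi$chrom[1], gi$start[1], gi$end[2], gi$strand[1],
        sample(active, 1), 3L, strand_code_zero = TRUE)
  }
  if (p$gene_ambiguous > 0) {
    reg_genes <- layout$gene_idx[layout$role == "regular"]
    made <- 0
    for (i in head(reg_genes, -1)) {
      if (made >= p$gene_ambiguous) break
      j <- i + 1
      if (!(j %in% reg_genes)) next
      if (layout$chrom[i] != layout$chrom[j] ||
          layout$strand[i] != layout$strand[j]) next
      gi <- introns[introns$gene_id == sprintf("G%03d", i), ]
      gj <- introns[introns$gene_id == sprintf("G%03d", j), ]
      if (nrow(gi) == 0 || nrow(gj) == 0) next
      st <- layout$strand[i]
      if (st == "+") {
        s <- gi$donor_pos[1]; e <- gj$acceptor_pos[1]
      } else {
        s <- gi$acceptor_pos[1]; e <- gj$donor_pos[1]
      }
      if (s >= e) next
      add("class_gene_ambiguous", gi$chrom[1], s, e, st, sample(active, 1), 3L)
      made <- made + 1
    }
  }
  for (k in seq_len(p$unannotated)) {
    s <- far[["chr1"]] + 20000L + k * 700L
    add("class_unannotated", "chr1", s, s + 80L, "+", sample(active, 1), 3L,
        strand_code_zero = TRUE)
  }

  # pairing plants
  detected <- long %>%
    filter(.data$kind == "annotated", .data$count >= 1,
           .data$sample_id %in% active)
  detected_key <- paste(detected$intron_id, detected$sample_id)
  amb_genes <- genes$gene_id[genes$role == "ambiguous"]
  for (g in amb_genes) {
    gi <- introns[introns$gene_id == g, ]
    # the two intron-1 variants share their genomic end (the acceptor on +,
    # the donor on -); a junction from a fresh left position to that shared
    # end has both introns as site-sharing candidates
    shared <- gi %>% count(.data$chrom, .data$strand, .data$end) %>%
      filter(n >= 2)
    if (nrow(shared) == 0) abort("ambiguity plant gene lacks a shared site")
    pair <- gi[gi$end == shared$end[1], ]
    ok <- active[purrr::map_lgl(active, function(smp) {
      all(paste(pair$intron_id, smp) %in% detected_key)
    })]
    if (length(ok) < 1) abort("ambiguity plant found no co-detected samples")
    smp <- sample(ok, min(3, length(ok)))
    novel_pos <- min(pair$start) - 40L
    add("pairing_ambiguous", pair$chrom[1], novel_pos, pair$end[1],
        pair$strand[1], smp, 1L + rpois(length(smp), 2))
  }
  unp_genes <- genes$gene_id[genes$role == "unpairable"]
  for (g in unp_genes) {
    gi <- introns[introns$gene_id == g, ]
    it <- gi[1, ]
    det <- detected$sample_id[detected$intron_id == it$intron_id]
    s0 <- setdiff(active, det)
    if (length(s0) == 0) {
      # force one sample to lack annotated evidence for this intron
      s0 <- active[1]
      long <- filter(long, !(.data$intron_id == it$intron_id &
                               .data$kind == "annotated" &
                               .data$sample_id == s0))
    } else {
      s0 <- s0[1]
    }
    novel_pos <- if (it$strand == "+") it$start - 43L else it$end + 43L
    add("pairing_unpairable", it$chrom,
        if (it$strand == "+") novel_pos else it$start,
        if (it$strand == "+") it$end else novel_pos,
        it$strand, s0, 2L)
  }
  hs_genes <- genes$gene_id[genes$role == "high_support"]
  hs <- p$high_support
  hs_registry <- tibble(junction_id = character(), tissue = character(),
                        target_pct = numeric(), realized_pct = numeric())
  for (g in head(hs_genes, hs$n)) {
    gi <- introns[introns$gene_id == g, ]
    it <- gi[1, ]
    tis <- sprintf("tissue_%02d", hs$tissue)
    smp_t <- samples$sample_id[samples$tissue == tis & !samples$excluded]
    n_det <- ceiling(hs$pct / 100 * length(smp_t))
    smp <- smp_t[seq_len(n_det)]
    missing_det <- smp[!paste(it$intron_id, smp) %in% detected_key]
    if (length(missing_det) > 0) {
      long <- bind_rows(long, tibble(
        chrom = it$chrom, start = it$start, end = it$end, strand = it$strand,
        sample_id = missing_det, count = 1L, kind = "annotated",
        intron_id = it$intron_id,
        junction_id = junction_coord_id(it$chrom, it$start, it$end, it$strand)))
    }
    novel_pos <- if (it$strand == "+") it$start - 37L else it$end + 37L
    jid <- add("high_support", it$chrom,
               if (it$strand == "+") novel_pos else it$start,
               if (it$strand == "+") it$end else novel_pos,
               it$strand, smp, 1L + rpois(length(smp), 2))
    hs_registry <- bind_rows(hs_registry, tibble(
      junction_id = jid, tissue = tis, target_pct = hs$pct,
      realized_pct = 100 * n_det / length(smp_t)))
  }

  list(long = bind_rows(rows), registries = reg, blacklist = blacklist,
       high_support = hs_registry, base_long = long)
}

# ---- ground truth --------------------------------------------------------

sim_truth <- function(config, samples, ann, rates, novel, cm, plants, long) {
  active <- samples %>% filter(!.data$excluded)
  long_active <- long %>% filter(.data$sample_id %in% active$sample_id)
  introns <- ann$introns
  p <- config$planted

  # pairing bookkeeping: candidate sets under the co-detection rule,
  # evaluated directly on the generated count matrix
  ann_detect <- long_active %>%
    filter(.data$kind == "annotated") %>%
    distinct(.data$intron_id, .data$sample_id)
  detect_key <- paste(ann_detect$intron_id, ann_detect$sample_id)
  novel_kinds <- c("novel_donor", "novel_acceptor", "pairing_ambiguous",
                   "pairing_unpairable", "high_support")
  novel_tab <- long_active %>%
    filter(.data$kind %in% novel_kinds) %>%
    group_by(.data$junction_id, .data$chrom, .data$strand, .data$start,
             .data$end, .data$kind) %>%
    summarise(samples = list(unique(.data$sample_id)), .groups = "drop")
  # novel side by construction; the ambiguity plant anchors at the shared
  # genomic end, which is the acceptor on + but the donor on -
  novel_tab$side <- dplyr::case_when(
    novel_tab$kind == "novel_acceptor" ~ "acceptor",
    novel_tab$kind == "pairing_ambiguous" & novel_tab$strand == "-" ~ "acceptor",
    TRUE ~ "donor")
  acceptor_map <- split(introns$intron_id,
                        paste(introns$chrom, introns$strand,
                              introns$acceptor_pos))
  donor_map <- split(introns$intron_id,
                     paste(introns$chrom, introns$strand, introns$donor_pos))
  status <- purrr::pmap(list(novel_tab$chrom, novel_tab$strand,
                             novel_tab$start, novel_tab$end,
                             novel_tab$side, novel_tab$samples),
                        function(chrom, strand, s, e, side, smp) {
    anchor <- if (side == "donor") {
      if (strand == "-") s else e        # acceptor end of a novel donor
    } else {
      if (strand == "-") e else s        # donor end of a novel acceptor
    }
    cand <- if (side == "donor") {
      acceptor_map[[paste(chrom, strand, anchor)]] %||% character()
    } else {
      donor_map[[paste(chrom, strand, anchor)]] %||% character()
    }
    keep <- cand[purrr::map_lgl(cand, function(ic) {
      all(paste(ic, smp) %in% detect_key)
    })]
    list(candidates = sort(keep),
         status = if (length(keep) == 1) "paired"
                  else if (length(keep) == 0) "unpairable" else "ambiguous")
  })
  novel_tab$status <- purrr::map_chr(status, "status")
  novel_tab$candidates <- purrr::map(status, "candidates")
  pairing_audit <- list(
    n_paired = sum(novel_tab$status == "paired"),
    n_unpairable = sum(novel_tab$status == "unpairable"),
    n_ambiguous = sum(novel_tab$status == "ambiguous"),
    dropped_intron_ids = sort(setdiff(
      unique(unlist(novel_tab$candidates[novel_tab$status == "ambiguous"])),
      purrr::map_chr(novel_tab$candidates[novel_tab$status == "paired"],
                     ~ .x[1]) %||% character())))

  # expected per-tissue MSR from the generated counts (ratio of sums over
  # the junctions that end up paired)
  paired <- novel_tab %>% filter(.data$status == "paired") %>%
    mutate(intron_id = purrr::map_chr(.data$candidates, 1))
  paired_counts <- long_active %>%
    filter(.data$junction_id %in% paired$junction_id) %>%
    left_join(select(paired, "junction_id", paired_intron = "intron_id",
                     "side"), by = "junction_id")
  smp_tissue <- setNames(active$tissue, active$sample_id)
  msr_expect <- purrr::map(split(active$sample_id, active$tissue),
                           function(smp) {
    s_tab <- long_active %>%
      filter(.data$kind == "annotated", .data$sample_id %in% smp) %>%
      group_by(.data$intron_id) %>%
      summarise(s = sum(.data$count), .groups = "drop")
    j_tab <- paired_counts %>%
      filter(.data$sample_id %in% smp) %>%
      group_by(intron_id = .data$paired_intron, .data$side) %>%
      summarise(j = sum(.data$count), .groups = "drop") %>%
      tidyr::pivot_wider(names_from = "side", values_from = "j",
                         values_fill = 0L)
    for (col in c("donor", "acceptor")) {
      if (!col %in% names(j_tab)) j_tab[[col]] <- 0L
    }
    s_tab %>%
      left_join(j_tab, by = "intron_id") %>%
      mutate(donor = dplyr::coalesce(.data$donor, 0L),
             acceptor = dplyr::coalesce(.data$acceptor, 0L),
             msr_d = .data$donor / (.data$donor + .data$s),
             msr_a = .data$acceptor / (.data$acceptor + .data$s))
  }) %>% bind_rows(.id = "tissue")

  expected_category_counts <- c(
    annotated = dplyr::n_distinct(
      long_active$junction_id[long_active$kind == "annotated"]),
    novel_donor = sum(novel_tab$side == "donor"),
    novel_acceptor = sum(novel_tab$side == "acceptor"),
    novel_combo = length(plants$registries$class_combo %||% character()),
    novel_exon_skip = length(plants$registries$class_exon_skip %||% character()),
    ambiguous_gene = length(plants$registries$class_gene_ambiguous %||% character()),
    unannotated = length(plants$registries$class_unannotated %||% character()))

  list(
    rates = rates %>%
      tidyr::crossing(tissue = unique(active$tissue)) %>%
      select("intron_id", "tissue", "p_d", "p_a"),
    novel_sites = novel,
    registries = plants$registries,
    high_support = plants$high_support,
    expected_filter_removals = c(
      min_length = length(plants$registries$qc_short %||% character()),
      chromosomes = length(plants$registries$qc_scaffold %||% character()),
      blacklist = length(plants$registries$qc_blacklist %||% character())),
    expected_category_counts = expected_category_counts,
    expected_pairing_audit = pairing_audit,
    expected_msr = msr_expect,
    novel_status = select(novel_tab, "junction_id", "kind", "side",
                          "status", "candidates"))
}

# ---- file writers --------------------------------------------------------

sim_write_outputs <- function(config, out_dir, samples, ann, layout, long,
                              plants, truth) {
  paths <- list()
  paths$samples <- file.path(out_dir, "samples.tsv")
  readr::write_tsv(samples, paths$samples)

  paths$gtf <- file.path(out_dir, "annotation.gtf")
  sim_write_gtf(ann, paths$gtf)

  paths$genome <- file.path(out_dir, "genome.fa")
  sim_write_genome(ann, long, paths$genome)

  paths$blacklist <- file.path(out_dir, "blacklist.bed")
  readr::write_tsv(plants$blacklist %>%
                     mutate(start = .data$start - 1L) %>%
                     select("chrom", "start", "end"),
                   paths$blacklist, col_names = FALSE)

  # per-sample STAR SJ.out.tab
  sj_dir <- file.path(out_dir, "junctions")
  manifest <- samples %>%
    mutate(path = file.path("junctions", paste0(.data$sample_id, ".SJ.out.tab")))
  for (i in seq_len(nrow(manifest))) {
    smp <- manifest$sample_id[i]
    tab <- long %>%
      filter(.data$sample_id == smp, .data$count > 0) %>%
      transmute(chrom = .data$chrom, start = .data$start, end = .data$end,
                strand_code = dplyr::case_when(.data$strand == "+" ~ 1L,
                                               .data$strand == "-" ~ 2L,
                                               TRUE ~ 0L),
                motif = 0L, annotated = 0L, n_unique = .data$count,
                n_multi = 0L, overhang = 30L) %>%
      arrange(.data$chrom, .data$start, .data$end, .data$strand_code)
    readr::write_tsv(tab, file.path(out_dir, manifest$path[i]),
                     col_names = FALSE)
  }
  paths$manifest <- file.path(out_dir, "manifest.tsv")
  readr::write_tsv(select(manifest, "sample_id", "path"), paths$manifest)

  # score tracks over the proximal windows
  win <- proximal_windows(ann$introns)
  pos_tab <- win %>%
    group_by(.data$chrom) %>%
    summarise(pos = list(unique(unlist(purrr::map2(.data$start, .data$end,
                                                   seq)))),
              .groups = "drop") %>%
    tidyr::unnest_longer("pos") %>%
    arrange(.data$chrom, .data$pos)
  paths$phastcons <- file.path(out_dir, "phastcons.tsv")
  readr::write_tsv(mutate(pos_tab, value = round(runif(n()), 4)),
                   paths$phastcons)
  paths$cdts <- file.path(out_dir, "cdts.tsv")
  readr::write_tsv(mutate(pos_tab, value = round(runif(n(), -1, 1), 4)),
                   paths$cdts)

  # synthetic join tables
  introns <- ann$introns
  n_clin <- min(5L, nrow(introns))
  clin_idx <- sample(seq_len(nrow(introns)), n_clin)
  paths$clinvar <- file.path(out_dir, "clinvar_synthetic.tsv")
  readr::write_tsv(tibble(
    chrom = introns$chrom[clin_idx],
    pos = as.integer((introns$start[clin_idx] + introns$end[clin_idx]) %/% 2),
    significance = "pathogenic"), paths$clinvar)

  iaod_keep <- runif(nrow(introns)) < 0.75
  paths$iaod <- file.path(out_dir, "iaod_synthetic.tsv")
  readr::write_tsv(tibble(
    chrom = introns$chrom[iaod_keep], start = introns$start[iaod_keep],
    end = introns$end[iaod_keep], strand = introns$strand[iaod_keep],
    u2_intron = runif(sum(iaod_keep)) > 0.06,
    u12_intron = FALSE) %>%
      mutate(u12_intron = !.data$u2_intron),
    paths$iaod)

  paths$tpm <- file.path(out_dir, "tpm.tsv")
  readr::write_tsv(tidyr::crossing(gene_id = ann$genes$gene_id,
                                   sample_id = samples$sample_id) %>%
                     mutate(tpm = round(stats::rgamma(n(), 2, scale = 20), 2)),
                   paths$tpm)
  paths
}

sim_write_gtf <- function(ann, path) {
  attr_gene <- function(g) {
    sprintf('gene_id "%s"; gene_name "%s"; gene_biotype "%s";',
            g$gene_id, g$symbol, g$biotype)
  }
  lines <- character()
  tx_by_gene <- split(ann$transcripts, ann$transcripts$gene_id)
  ex_by_tx <- split(ann$exons, ann$exons$transcript_id)
  genes <- ann$genes %>% arrange(.data$chrom, .data$start)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, paste(g$chrom, "sim", "gene", g$start, g$end, ".",
                            g$strand, ".", attr_gene(g), sep = "\t"))
    txs <- tx_by_gene[[g$gene_id]]
    for (k in seq_len(nrow(txs))) {
      tx <- txs[k, ]
      ex <- ex_by_tx[[tx$transcript_id]] %>% arrange(.data$start)
      tsl_str <- if (is.na(tx$tsl)) "NA" else as.character(tx$tsl)
      attrs <- sprintf(paste0('gene_id "%s"; transcript_id "%s"; ',
                              'gene_biotype "%s"; transcript_biotype "%s"; ',
                              'transcript_support_level "%s"; tag "basic";%s'),
                       g$gene_id, tx$transcript_id, g$biotype, tx$biotype,
                       tsl_str,
                       if (tx$is_mane_select) ' tag "MANE_Select";' else "")
      lines <- c(lines, paste(g$chrom, "sim", "transcript", min(ex$start),
                              max(ex$end), ".", g$strand, ".", attrs,
                              sep = "\t"))
      ranks <- if (g$strand == "-") rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
      for (e in seq_len(nrow(ex))) {
        eattrs <- sprintf('gene_id "%s"; transcript_id "%s"; exon_number "%d";',
                          g$gene_id, tx$transcript_id, ranks[e])
        lines <- c(lines, paste(g$chrom, "sim", "exon", ex$start[e],
                                ex$end[e], ".", g$strand, ".", eattrs,
                                sep = "\t"))
      }
    }
  }
  readr::write_lines(lines, path)
}

# random background with GT/AG (strand-oriented) planted at every annotated
# splice site, so sequence windows have realistic anchors
sim_write_genome <- function(ann, long, path) {
  need <- bind_rows(
    select(ann$genes, "chrom", pos = "end"),
    long %>% filter(.data$chrom %in% default_chromosomes()) %>%
      select("chrom", pos = "end")) %>%
    group_by(.data$chrom) %>%
    summarise(len = max(.data$pos) + 3000L, .groups = "drop")
  seqs <- purrr::map(seq_len(nrow(need)), function(i) {
    len <- need$len[i]
    bases <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    here <- ann$introns[ann$introns$chrom == need$chrom[i], ]
    for (k in seq_len(nrow(here))) {
      it <- here[k, ]
      if (it$strand == "+") {
        bases[it$start] <- "G"; bases[it$start + 1L] <- "T"
        bases[it$end - 1L] <- "A"; bases[it$end] <- "G"
      } else {
        bases[it$end] <- "C"; bases[it$end - 1L] <- "A"
        bases[it$start] <- "C"; bases[it$start + 1L] <- "T"
      }
    }
    paste(bases, collapse = "")
  })
  dna <- Biostrings::DNAStringSet(unlist(seqs))
  names(dna) <- need$chrom
  Biostrings::writeXStringSet(dna, path, width = 80L)
  invisible(path)
}

#' Verify a pipeline run against the synthetic ground truth
#'
#' Compares a [run_splice_pipeline()] result on simulated data with the
#' generator's manifest: per-filter removal counts and the pairing audit
#' must match exactly; the per-tissue mis-splicing ratios must equal the
#' manifest's ratio-of-sums bookkeeping to numerical precision; recovered
#' ratios must lie within a binomial-error band of the true simulated
#' rates; and the planted high-support junction must be recovered by the
#' support filter at its target threshold.
#'
#' @param build A `splice_build` from [run_splice_pipeline()].
#' @param truth The `truth` element of [simulate_splicing_dataset()].
#' @param rate_tolerance Floor of the absolute tolerance for rate recovery;
#'   the effective per-intron band is
#'   `max(rate_tolerance, 5 * sqrt(p (1 - p) / n_events))`.
#' @return Tibble with columns `check`, `pass`, `detail`.
#' @export
verify_against_truth <- function(build, truth, rate_tolerance = 0.02) {
  checks <- list()
  note <- function(check, pass, detail = "") {
    checks[[length(checks) + 1]] <<- tibble(check = check, pass = pass,
                                            detail = detail)
  }

  removed <- setNames(build$qc_audit$n_removed, build$qc_audit$step)
  exp_rm <- truth$expected_filter_removals
  note("qc_filter_removals",
       all(removed[names(exp_rm)] == exp_rm),
       paste(names(exp_rm), removed[names(exp_rm)], "vs", exp_rm,
             collapse = "; "))

  cat_counts <- table(factor(build$classified$category,
                             levels = junction_categories()))
  exp_cat <- truth$expected_category_counts
  note("classification_counts",
       all(as.integer(cat_counts[names(exp_cat)]) == exp_cat),
       paste(names(exp_cat), as.integer(cat_counts[names(exp_cat)]), "vs",
             exp_cat, collapse = "; "))

  aud <- build$pairing_audit
  exp_aud <- truth$expected_pairing_audit
  note("pairing_audit",
       aud$n_paired == exp_aud$n_paired &&
         aud$n_unpairable == exp_aud$n_unpairable &&
         aud$n_ambiguous == exp_aud$n_ambiguous &&
         setequal(aud$dropped_intron_ids, exp_aud$dropped_intron_ids),
       sprintf("paired %d/%d unpairable %d/%d ambiguous %d/%d",
               aud$n_paired, exp_aud$n_paired,
               aud$n_unpairable, exp_aud$n_unpairable,
               aud$n_ambiguous, exp_aud$n_ambiguous))

  exp_msr <- truth$expected_msr %>%
    filter(!.data$intron_id %in% exp_aud$dropped_intron_ids)
  cmp <- inner_join(select(build$intron_stats, "intron_id", "tissue",
                           "msr_d", "msr_a"),
                    select(exp_msr, "intron_id", "tissue",
                           exp_msr_d = "msr_d", exp_msr_a = "msr_a"),
                    by = c("intron_id", "tissue"))
  max_diff <- max(c(abs(cmp$msr_d - cmp$exp_msr_d),
                    abs(cmp$msr_a - cmp$exp_msr_a), 0))
  note("msr_bookkeeping",
       nrow(cmp) == nrow(exp_msr) &&
         nrow(cmp) == nrow(build$intron_stats) && max_diff < 1e-12,
       sprintf("%d of %d records, max |diff| = %.3g",
               nrow(cmp), nrow(exp_msr), max_diff))

  # introns parenting planted junctions (novel-transcript plants, not
  # mis-splicing) are exempt from rate recovery
  plant_parents <- truth$novel_status %>%
    filter(.data$kind %in% c("high_support", "pairing_unpairable",
                             "pairing_ambiguous")) %>%
    pull("candidates") %>% unlist() %>% unique()
  rates <- truth$rates %>%
    filter(!.data$intron_id %in% exp_aud$dropped_intron_ids,
           !.data$intron_id %in% plant_parents)
  rec <- inner_join(build$intron_stats, rates, by = c("intron_id", "tissue")) %>%
    mutate(n_events_d = .data$sum_novel_donor_reads + .data$sum_annotated_reads,
           tol_d = pmax(rate_tolerance,
                        5 * sqrt(.data$p_d * (1 - .data$p_d) / .data$n_events_d)),
           ok_d = abs(.data$msr_d - .data$p_d) <= .data$tol_d,
           zero_ok = .data$p_d > 0 | .data$msr_d == 0)
  note("rate_recovery",
       all(rec$ok_d) && all(rec$zero_ok),
       sprintf("max |msr_d - p_d| = %.4f over %d records",
               max(abs(rec$msr_d - rec$p_d), 0), nrow(rec)))

  if (nrow(truth$high_support) > 0) {
    hs <- truth$high_support
    got <- purrr::map2_lgl(hs$junction_id, seq_len(nrow(hs)), function(j, i) {
      sel <- support_filter(build$novel_stats, hs$target_pct[i],
                            tissue = hs$tissue[i])
      j %in% sel
    })
    note("support_filter", all(got),
         sprintf("%d of %d planted high-support junctions recovered",
                 sum(got), nrow(hs)))
  }

  bind_rows(checks)
}
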