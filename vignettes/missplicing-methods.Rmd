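---
title: "Methods: junction quality control, classification, pairing and mis-splicing ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: junction quality control, classification, pairing and mis-splicing ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, conventions and design decisions
behind `intronaut`, in the spirit of a statistical methods section: what
each stage assumes, which parameters matter, and what the test suite does
and does not demonstrate.

## Coordinates and the intron catalogue

All intervals are 1-based and inclusive, spanning the first to the last
intronic base — the convention of STAR's `SJ.out.tab`. BED inputs
(0-based, half-open) are converted on ingestion. An intron is the gap
between two consecutive exons of one transcript,
`[prev_exon_end + 1, next_exon_start - 1]`; abutting or overlapping exon
pairs contribute no intron and are reported as a warning rather than an
error, since real annotations contain them. Identical intron coordinates
within one gene are collapsed into a single catalogue entry accumulating
all parent transcripts; the same coordinates under two gene identifiers
are kept once per gene, because downstream gene-level statistics would
otherwise be ill-defined.

Donor and acceptor are transcriptional notions: on `+` the donor is the
interval start, on `-` the interval end. Every operation downstream
(classification, windows, distances) is written against these
strand-aware positions, and the strand-mirror property — flipping the
strand of an annotation swaps every donor with its acceptor and mirrors
every window — is asserted in the tests.

Transcript support level (TSL) is summarised per intron as the *best*
(numerically smallest) level among parent transcripts, because TSL 1
denotes the strongest evidence grade. Since one could also read an
intron-level "maximum TSL" as the literal numeric maximum, the summary is
switchable (`tsl_policy = "best"` or `"worst"`); the default is the
reading under which the value describes the best-supported context the
intron occurs in. Introns whose parents all lack a TSL report `NA`. The
percentage of protein-coding transcripts containing an intron uses the
gene's protein-coding transcripts as denominator and is defined as 0 for
genes with none (e.g. lncRNA genes) rather than undefined.

## Junction quality control

Three filters, applied to the merged junction table:

* **Minimum implied intron length**, default 25 bp: the shortest span
  that can still contain the donor site, branch point and acceptor
  signals. The boundary is inclusive — 25 bp survives, 24 bp does not.
* **Contig whitelist**, default `chr1`–`chr22`, `chrX`, `chrY`:
  junctions on unplaced or unlocalized scaffolds (and `chrM`) cannot be
  ordered and oriented within the primary assembly and are removed.
* **Blacklist overlap**: any shared base between the implied intron span
  (closed interval) and a blacklist interval removes the junction;
  abutting intervals do not intersect. Whether the original analyses
  tested the whole span or only the splice-site bases is not decidable
  from their description, so `blacklist_mode = "span"` (default) and
  `"ends"` are both available; the span reading is the default because
  the implied intron is the only coordinate footprint a junction retains.

The filters commute; the fixed order (length, scaffolds, blacklist) only
determines how removals are attributed in the audit. Counts are stored
sparsely: absence of a `(junction, sample)` row means zero reads, and
zero-count input rows are dropped at parse time. The same sample
appearing twice in a manifest is a hard error — counts are never silently
summed.

## Classification

Matching is exact at base-pair resolution, with no tolerance window:
"the donor end matches" means an annotated intron has its donor at
exactly that position, on that strand and contig. The decision procedure
per junction:

1. exact span match → `annotated`;
2. exactly one end matches its expected site kind → `novel_donor`
   (unannotated donor end) or `novel_acceptor` (unannotated acceptor
   end); if that single end matches sites of more than one gene the
   junction is `ambiguous_gene`;
3. both ends match sites of a common gene but the pair is not an
   annotated intron → `novel_exon_skip` when the span fully contains at
   least one internal annotated exon of that gene, else `novel_combo`;
4. end matches involve only different genes, or only the opposite
   strand → `ambiguous_gene`;
5. no match → `unannotated`.

Unknown-strand junctions (STAR strand code 0, common with unstranded
libraries) are evaluated on both strands; a unique matching strand
resolves the junction, matches on both strands make it `ambiguous_gene`.
Only `annotated`, `novel_donor` and `novel_acceptor` are carried forward
— the remaining categories cannot be tied to a unique annotated intron
and are tallied and dropped. The exon-skip/combo split follows the
published semantics of the upstream classification tool as we read them
(contains-a-complete-internal-exon test); both categories are discarded,
so this interpretation affects only audit counts.

## Pairing and the co-detection rule

A novel donor (acceptor) junction shares its annotated acceptor (donor)
site with one or more catalogue introns. A candidate parent must
additionally satisfy **co-detection**: at least one annotated read in
*every* sample — pooled across all tissues — in which the novel junction
was observed. Exactly one surviving candidate yields a pair; zero makes
the junction unpairable; two or more make it ambiguous, and ambiguous
junctions are discarded outright. No tie-breaking by read support or
intron length is attempted: the premise that mis-splicing is the
inaccurate excision of a *single* annotated intron means a junction whose
parent cannot be determined carries no usable signal.

Introns that appear only in ambiguous junctions' candidate sets — and end
up parenting nothing — are excluded from the mis-splicing tables
(`drop_parenting_introns = TRUE`), since every observation of novel
activity at their sites was discarded as unattributable; introns with no
novel activity at all are kept, as accurate splicing is itself a result.
The original description of this exclusion is ambiguous, so the behaviour
is switchable.

## The mis-splicing ratio

With `j_i` the novel donor reads of intron X's children and `s_i` its
annotated reads in sample `i` of a tissue:

$$MSR_D^X = \frac{\sum_{i=1}^{N} j_i}{\sum_{i=1}^{N} j_i + \sum_{i=1}^{N} s_i}$$

and symmetrically for `MSR_A`. Two deliberate choices:

* **Denominator.** The displayed formula divides by same-side novel plus
  annotated reads; a prose reading ("all annotated intron and novel
  junction read counts") would pool both sides. The formula is the more
  precise statement and is the default (`msr_denominator = "same_side"`);
  `"both_sides"` implements the prose reading.
* **Detection.** A ratio is emitted only when the intron is detected in
  the tissue. The default `detection_rule = "annotated_reads"` requires
  at least one annotated read, which guarantees a positive denominator
  and gives the estimator a ceiling strictly below 1;
  `"any_supporting_reads"` admits introns seen only through novel reads
  (their same-side ratio is then 1, or undefined — reported `NA` — if
  only the opposite side was seen).

The ratio is a pooled ratio of sums, not a mean of per-sample ratios;
with equal per-sample depth it equals the depth-weighted mean of
per-sample ratios (asserted in tests). It is invariant under uniform
scaling of all counts, and exactly 0 — not approximately — when no novel
children exist. As a plug-in binomial estimator its standard error is
roughly `sqrt(p(1-p)/n)` for `n` pooled events, which is what the
parameter-recovery tests bound against.

Frameshift capability of a novel junction is `|d| mod 3 ∈ {1, 2}` where
`d` is the distance between the novel splice site and the corresponding
annotated site of its parent. The absolute value is taken before the
modulo because signed-modulo conventions differ between languages; the
sign (positive = downstream in transcriptional direction) is retained
separately for display.

## Sequence windows and scoring

Splice-site strength windows follow the standard maximum-entropy model
conventions: the donor window is 9 bp (3 exonic + 6 intronic), the
acceptor window 23 bp (20 intronic + 3 exonic), both strand-oriented and
reverse-complemented on `-`. The sources we implement give only the
window lengths, so the exon/intron split is adopted from the scoring
algorithm those lengths imply. Scoring is a pluggable contract
(`score_donor(9-mer)`, `score_acceptor(23-mer)`); the package ships a
deterministic consensus position-weight-matrix log-odds scorer, and any
wrapper with the same signature (for example around externally supplied
maximum-entropy model tables) can be substituted. Sequences containing
`N` score `NA` rather than being imputed.

Proximal conservation/constraint windows are 40 bp: 5 exonic + 35
intronic at the 5' side, 35 intronic + 5 exonic at the 3' side, with the
boundary base counted inside the 35-bp intronic portion. Introns shorter
than 35 bp truncate the intronic portion at the opposite splice site and
are flagged. Track means are arithmetic means over non-missing bases —
missing bases are excluded, not treated as zero, because per-base score
dumps legitimately omit positions; a fully missing window yields `NA`.

## The synthetic data generator

The generator emulates the statistical structure the pipeline assumes,
not raw sequencing. Per intron and sample, total splicing events are
`T ~ Poisson(λ)` (negative binomial optionally, for overdispersion
robustness checks); each event is a donor mis-splice, acceptor mis-splice
or accurate splice with probabilities
`a = p_D(1-p_A)/(1-p_D p_A)`, `b = p_A(1-p_D)/(1-p_D p_A)`, so that the
pooled ratio-of-sums estimators converge exactly to the per-intron true
rates `(p_D, p_A)` despite the shared annotated-read denominator. True
rates follow a zero-inflated Beta: a point mass at 0 (probability 0.3 by
default — a substantial fraction of introns splice perfectly) and
`Beta(1.5, 30)` otherwise (mean ≈ 0.05, right-skewed: mis-splicing is
usually rare but occasionally substantial). The default study conditions
are 3 tissues × 10 samples (plus 2 excluded samples), 50 genes and
λ = 100 annotated reads per intron and sample — small enough to run in
seconds, deep enough that every detection rule engages.

Novel splice sites sit at fixed genomic offsets (3–30 bp) from their
annotated site, chosen to avoid every annotated splice-site position; the
in-frame fraction then arises naturally (~1/3). Planted cases cover
every branch: junctions failing exactly one QC filter each (registries
are disjoint by construction so per-filter removal counts are exact),
one junction per discarded classification category, ambiguous-pairing
cases built from alternative-donor gene models whose two introns share a
genomic end, unpairable cases whose only compatible intron lacks
annotated reads in the planted sample, and one high-support junction
present in 90% of one tissue's samples. The truth manifest's expected
audit and expected ratios are computed by direct bookkeeping on the
generated count tables — an independent, loop-based re-derivation that
serves as the oracle for the pipeline's set-based implementation. The toy
genome is random sequence with GT/AG dinucleotides planted at every
splice site, so sequence windows have realistic anchors.

What the generator does **not** emulate: read-level artefacts (alignment
error, multi-mapping, overhang effects), expression heterogeneity across
genes, correlated mis-splicing between introns, and tissue-specific rate
differences. Passing tests therefore demonstrate the correctness of the
bookkeeping, classification, pairing logic and estimator — not robustness
to alignment noise, which is upstream of this pipeline's inputs.

## Numerical and degenerate-input choices

* Identifiers are coordinate-derived strings, so repeated runs are
  byte-identical; determinism end-to-end (simulate → build → export) is
  asserted by file hashing.
* Ratios and percentages are kept at full double precision in memory and
  in the database; rendering happens only at export.
* SQLite stores logicals as integers; the database embeds a
  `schema_types` table and `read_db_table()` restores the original
  column types, making round-trips bit-identical.
* Empty inputs (no junctions, no novel pairs, empty blacklist, header-only
  metadata) flow through every stage as empty tibbles rather than errors.
* A novel site coinciding with its annotated site, a duplicated novel
  junction across pairs, or a foreign-key violation at database load are
  internal errors — they indicate corrupted inputs or a logic fault, not
  analysable data.

## Test problem sizes

The suite simulates the default conditions above once and reuses them
across files; classification equivalence is checked against a brute-force
oracle on 1,000 randomised junctions over a ~50-intron catalogue; rate
recovery uses 1 tissue × 50 samples at λ = 200 with fixed rates
`{0.01, 0.1, 0.5, 0}` over ~110 introns, bounding the estimator within
±0.02 for introns with ≥ 10⁴ pooled events; frameshift logic is checked
exhaustively for distances 1–300. These sizes were chosen so the complete
suite exercises every branch while remaining a sub-minute run.

## Known limitations

* GTF (Ensembl attribute dialect) only; no GFF3, trans-splicing or
  fusion annotations.
* No BAM parsing: junction extraction from alignments is upstream.
* No per-sample ratios, no differential mis-splicing tests between
  tissues — the statistics are descriptive by design.
* The multi-valued GTF `tag` attribute is collapsed by the underlying
  importer; MANE Select status is recovered by a targeted scan, and an
  external MANE join table is accepted as a fallback.
* Ambiguous novel junctions are discarded, not probabilistically
  assigned; with deeply paralogous gene families this loses real signal.
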