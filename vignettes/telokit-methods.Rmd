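---
title: "Methods: TE-derived transcript discovery and quantification with telokit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TE-derived transcript discovery and quantification with telokit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(telokit)
library(dplyr)
```

`telokit` identifies transcriptionally active, locus-specific
transposable-element (TE) derived transcripts from long-read RNA-seq
alignments and quantifies them per cell in barcoded single-cell data.
This vignette is the package's account of the underlying procedure: the
model and its assumptions, the parameters that matter, the design
choices that were genuinely open, and what the synthetic fixtures do
and do not demonstrate.

## Coordinates and formats

All internal coordinates are 0-based half-open (`start` inclusive,
`end` exclusive), the SAM/BED convention; conversion happens only at
file boundaries. The UCSC RepeatMasker table dialect is already
half-open; RepeatMasker `.out` reports are 1-based inclusive and are
shifted on input, with the `C` strand mark mapped to `-`. GTF
coordinates are converted in both directions so that
`read_gtf(write_gtf(x))` is the identity.

Repeat taxonomy follows RepeatMasker's three levels —
subfamily (`repName`, e.g. AluY), family (`repFamily`, e.g. Alu) and
superfamily (`repClass`, e.g. SINE). The TE superfamily set is
`{LINE, SINE, LTR, DNA, RC, Retroposon}`; a trailing `?` in `repClass`
is stripped before matching, and `?`-suffixed or `Unknown` classes that
do not resolve to this set are excluded (the class set is an argument
of `read_repeatmasker()` for users who want them). Non-TE repeats —
simple repeats, low-complexity runs, tRNA-derived SINE-like entries,
satellites — are excluded from every TE computation. Rolling-circle
(`RC`, Helitron) elements are retained as TEs and reported under `DNA`
in superfamily summaries, the common convention for five-way summaries.

## Genome masks and read classification

The classifier's overlap oracle is a per-chromosome binary vector: a
base is 1 iff at least one annotation interval covers it. Four masks
are built once per run: all TE bases; TE bases of intergenic elements;
TE bases of intragenic elements; and nonTE exon bases. An element is
*intragenic* when it overlaps any gene's full transcript span by at
least one base (element-level labeling, so intronic TEs are
intragenic); "gene overlap" in the read rules, by contrast, means
overlap with the *exon* mask, because exonic sequence is what a
spliced read can actually share with a gene. Masks are unstranded:
strand is honored only in splice-site extraction.

Alignment filtering keeps primary, mapped records with MAPQ at or
above 30 and no hard clips. MAPQ ≥ 30 on a primary alignment is the
operational definition of "uniquely mapped"; hard-clipped records are
excluded because long-read aligners typically hard-clip when they
realign a read whose original placement was poor. Reference-consuming
blocks come from the CIGAR: `M/=/X/D` extend a block (a deletion lies
under the alignment footprint and bridges, never splits), `N` splits
blocks at introns, `I/S/H` consume no reference. The *aligned length*
is the total block width — it therefore includes deleted reference
bases and excludes skipped introns.

A TE-overlapping read is assigned exactly one category, tested in the
precedence order 1 → 3 → 2 → 4:

1. **intergenic** — no exon overlap, intergenic-TE overlap, and no
   intragenic-TE overlap. The zero-intragenic requirement reads
   "overlapped *only* with an intergenic TE region" literally; a read
   touching both an intergenic element and an intronic element falls
   to category 4.
2. **intragenic** — exon overlap and intragenic-TE overlap strictly
   above 80% of the aligned length. The threshold is strict: a read at
   exactly 0.80 is category 4. `te_frac_min` is exposed; raising it
   can only move reads from 2 to 4, never the reverse.
3. **fusion** — exon overlap and intergenic-TE overlap, regardless of
   the intragenic fraction. Fusion outranks intragenic because its
   definition is the intragenic pattern *plus* an intergenic element.
4. **other** — the catch-all. These reads span TE and gene context too
   ambiguously to anchor an assembly, so only categories 1–3 are
   merged into the assembler input.

Transcript assembly itself is delegated to an external long-read
assembler; `stringtie_command()` formats the documented invocation
(`-L -G guide.gtf -v -p 12 -j 1 -g 0 -f 0.01 -l STRG -m 50 -t -c 1.5
-s 1.5`) and `build_guide_annotation()` produces its guide — the gene
annotation plus one single-exon model per repeat element. No test or
pipeline stage executes the assembler; the annotator consumes any GTF.

## TE composition, naming, and the annotation summary

A transcript's TE composition is computed exon-wise: each subfamily's
copies are unioned, intersected with the union of the transcript's
exons, and measured in base pairs; intronic repeat bases never count,
and overlapping copies of one subfamily are not double-counted.
Percentages are relative to the **mature length** (sum of exon widths)
rather than the genomic span — the annotation describes transcripts,
not loci — and the span-based alternative can be derived from the
reported bp values if needed. Subfamilies are ordered by decreasing
percentage with alphabetical tie-break, which makes display names
(`STRG.1_AluY_L1PA3`) deterministic. Subfamily names are sanitized to
`[A-Za-z0-9.-]` before joining with `_`. The transcript's superfamily
is the class with the greatest summed overlap, ties broken by the
fixed order LINE > SINE > LTR > DNA > Retroposon; the tie order is a
convention and is documented rather than configurable.

`summarize_annotation()` reports gene counts, the isoform-count
histogram, and transcript-level superfamily counts/proportions;
`transcript_metrics()` adds mature length, genomic span, and the
1-based transcription end site (last exon end on `+`, first exon start
on `-`).

## Splice-site information content

For every intron of a multi-exon transcript, the donor window covers
the last 3 exonic plus first 6 intronic bases and the acceptor window
the last 6 intronic plus first 3 exonic bases, in transcript
orientation (minus-strand windows are mirrored and
reverse-complemented). The window widths are a package choice — wide
enough to bracket the GT/AG dinucleotides with context — and are
arguments of `extract_splice_sites()`. Counts become probabilities per
position, and information content is `p · (2 − H)` bits with `H` the
positional Shannon entropy (`0·log 0 = 0`). No pseudocounts are added:
the transform is descriptive, not inferential, and empty columns are
zeros. Both the probability and information layers are emitted because
"entropy" and "information content" are often conflated in logo
figures; `IC` per position always sums to `2 − H ≤ 2`, with 2 bits
meaning a perfectly conserved base. Sequences containing `N` are kept;
`N` is simply not tallied.

```{r motif-example}
ref <- simulate_reference(seed = 1)
sites <- extract_splice_sites(bind_rows(ref$genes, ref$assembled),
                              ref$genome)
information_matrix(counts_matrix(sites$donors))[4:5, ]
```

Every simulated intron is canonical, so the intronic GT positions carry
exactly 2 bits — the desk-scale analogue of splice-consensus validation
on a real annotation.

## Single-cell quantification

Before counting, TE transcripts with any exonic base shared with a
nonTE gene exon are removed (strand-agnostic, exon-level). This is
deliberately conservative: reads from shared regions are thereby
assigned to the gene annotation, at the cost of discarding genuinely
TE-derived transcripts that exonize into genes. Assignment within the
transcript layer follows three rules the package states explicitly
because no single convention is standard: candidates are collected by
block/exon overlap; if any candidate is a nonTE gene, TE candidates are
dropped; the surviving gene id must be unique (otherwise the read is
ambiguous and unassigned in this layer), and the read then counts
toward the gene and toward the single isoform with maximal overlap bp
(on an isoform tie, the gene alone is counted). The repeat-element
layer is independent: a read counts toward every element it overlaps by
one base, and those counts go to a separate matrix so the transcript
matrix stays shape-compatible with downstream tools. Intron-only
overlap never assigns a read, consistent with the bulk classifier.

UMI collapsing is exact-match on the `UB` string — one count per
distinct (barcode, feature, UMI) triple — so duplicating every input
record is a no-op. One-mismatch UMI merging is a possible extension,
not implemented. Reads lacking `CB`/`UB` are tallied and skipped;
barcodes outside the whitelist (when given) are discarded. The stats
block is an exact partition of scanned records (filtered, no-tag,
not-whitelisted, no-feature, ambiguous, assigned), so alternative
assignment policies can be compared honestly.

## Cohort statistics

Normalization scales each cell to the median of per-cell totals and
applies `log(1+x)`; the median target mirrors the default of the
standard single-cell toolchain and can be overridden with
`target_sum`. Zero-total cells stay zero with a warning. Per-cell TE
fraction defaults to the *features* reading (TE share of detected
features) with a *umis* mode; per-tissue TE sets threshold the summed
normalized expression at 100 by default (a raw-count mode exists), and
intersections are reported as exact exclusive partitions over all
tissue combinations.

Marker detection is a one-vs-rest Wilcoxon rank-sum test per feature
and cell type, using the tie-corrected normal approximation
`z = (R − μ)/σ`, `μ = n₁(n₁+n₂+1)/2`,
`σ² = (n₁n₂/12)·((n+1) − Σ(t³−t)/(n(n−1)))`, two-sided p, and
Benjamini–Hochberg adjustment across features within each cell type
(`stats::wilcox.test` with the same approximation is the test-suite
oracle). Log fold changes are computed on `expm1` of the group means
with a 1e-9 floor. TE-derived markers are rows whose feature id
contains `STRG.` with adjusted p below `alpha` (default 0.05). A
caveat the tests make visible: with a strongly planted marker,
total-count normalization shifts *all* other features of the marker's
cell type, so background features can be genuinely (and correctly)
significant under the null of equal normalized expression — type-I
calibration must be assessed on matrices without planted effects.

## The synthetic fixture generator

`simulate_reference()` lays each chromosome out in 2 kb tiles. Gene
tiles hold a two-exon gene cycling through four types: first exon 80%
covered by a TE (for intragenic reads), intronic TE, fusion (a clean
gene with an upstream intergenic element in the same tile), and clean.
TE tiles hold up to three intergenic elements; the first slot is a
fixed 600 bp element that can host "assembled" STRG transcript models
with up to three isoforms whose second exons are disjoint, so isoform
assignment has a unique truth. Every gene and STRG intron is patched
to canonical GT..AG in transcript orientation. Defaults are 2
chromosomes × 100 kb, 20 genes, 200 TE copies with class mix LINE 0.3,
SINE 0.3, LTR 0.2, DNA 0.1, Retroposon 0.1 — proportions chosen once
as a plausible miniature of the human repeat landscape — and 12 STRG
models. All randomness flows through one seed; identical seeds give
byte-identical files.

`simulate_long_reads()` engineers reads to satisfy exactly one
category definition, including decoys at *exactly* the 0.80 boundary
(truth: category 4, by strictness), sub-0.8 fraction reads,
intronic-TE-only reads, and filter decoys (MAPQ 10, hard-clipped,
secondary, unmapped). `simulate_barcoded_reads()` draws molecules
Poisson per cell and gene, emits 1–3 duplicate reads per molecule with
shared CB/UB tags, and records molecule truth over the same feature
universe the quantifier reports. `simulate_expression_matrix()` skips
the read level entirely for statistics work where hundreds of
replicates are needed.

What the fixtures do **not** emulate: sequencing error and soft-clip
noise at realistic rates, repeat copies that diverge from a consensus
(every element is just a labeled interval), multi-mapping ambiguity,
barcode errors, or ambient RNA. Passing tests therefore demonstrate
the correctness of the decision logic, coordinate arithmetic,
deduplication and statistics — not robustness to alignment noise on
real data.

## Problem sizes and numerical choices

The validation suite runs at desk scale by design: 1,000 reads against
a per-base brute-force classifier on the 2×100 kb toy genome, five
seeded truth-recovery replicates of 160 reads plus decoys, 100 random
mask instances against naive per-base oracles, exact-recovery
quantification over 20 cells with 3× read duplication, 20 power
replicates and 100 null replicates for marker calibration (30 vs 120
cells, Poisson mean 20 vs 0). These sizes were chosen as the smallest
that exercise every rule, boundary and tie; all are parameters of the
generator, so larger runs are one argument away.

Numerical conventions worth stating: the 80% rule is strict (`>`); the
category precedence is fixed; empty motif columns are zeros, not
errors; BH is applied within each cell type; rank-sum `σ² ≤ 0`
(all-tied feature) yields `z = 0`, `p = 1`; pipeline stages are
re-executed whenever their recorded output checksums no longer match
the manifest, which makes a corrupted intermediate self-healing rather
than fatal.

## Known limitations

Chromosome-length logical masks favor clarity over memory; at full
human-genome scale a bit-packed backend would be the natural upgrade.
Multi-mapping reads are discarded rather than rescued by an EM
reallocation, so young, highly identical subfamilies (L1HS, AluYa5)
are under-counted — an inherent property of the MAPQ-30 uniqueness
proxy. The conservative exon-overlap reconciliation removes genuine
gene-exonizing TE transcripts from single-cell counting. Fractional or
per-layer read allocation policies other than the stated one are not
implemented, but the stats partition makes room to compare them.
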