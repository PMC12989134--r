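---
title: "Smart-seq3 UMI quantification with umiquant: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smart-seq3 UMI quantification with umiquant: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

umiquant quantifies Smart-seq3 libraries in two stages: UMI extraction from
raw paired FASTQ, and gene-level counting from aligned BAM plus a GTF. This
vignette explains the model behind each stage, the parameters that matter,
the numerical and design choices made where more than one reasonable option
existed, and what the synthetic-data generator does and does not emulate.

## The read model

Smart-seq3 5' reads begin with a template-switching-oligo *anchor*
(`ATTGCGCAATG`, 11 nt), followed by the UMI (8 nt by default) and a `GGG`
*trailing* trinucleotide added during reverse transcription; the cDNA
fragment follows. Ordinary internal reads carry no construct. Read 2 is
never scanned — the construct sits on the 5' read only.

`scan_anchor()` runs two phases:

* **strict** — exact anchor at offset 0 and exact trailing immediately
  after the UMI window. This is the position-based detection that
  sequencing errors defeat.
* **fuzzy** — start offsets `0..max_shift` scanned in increasing order; the
  first offset whose anchor window is within `max_anchor_mismatches`
  (Hamming) and whose trailing window is within `max_trailing_mismatches`
  wins.

The fuzzy model is *bounded Hamming distance within a bounded offset
window*: substitutions and small shifts are tolerated, insertions or
deletions inside the anchor are not. This keeps the matcher linear-time,
deterministic, and exactly checkable against a brute-force enumerator;
indel tolerance (edit distance) is an explicit non-goal. Defaults — one
anchor mismatch, one trailing mismatch, shift up to 2 nt — are deliberately
conservative: one substitution is by far the dominant error mode, and a
random 11-mer lies within one mismatch of the anchor with probability
~8×10⁻⁶, so false rescues of internal reads are rare (they do occur at that
rate; the per-read truth comparisons in the test suite account for it).
All thresholds are exposed in `extraction_config()`.

Tie-breaking is leftmost-offset first: the biologically expected position
wins, and the scan is reproducible. Within one offset there is only one
window, so no further tie-break is needed.

**N handling.** A construct hit whose UMI window contains `N` is *rejected*,
not counted as internal: the read demonstrably carries a UMI, but one that
cannot participate in deduplication; calling it internal would inflate the
internal tables. Rejected pairs can be diverted to their own FASTQ pair.

**UMI carriage.** The UMI is appended to the read identifier as
`<id>_<UMI>` (the UMI-tools convention) on both mates, so any aligner
preserves it without special flags. Quality strings are trimmed in lockstep
with the sequence; no quality-based filtering is performed — that belongs
to upstream QC.

## Feature index and pair classification

`parse_gtf()` reduces the annotation to one model per gene: the gene span
(from the `gene` line, or the exon hull when absent) and the merged union
of exons across all transcripts. Intron territory is *span minus exon
union*; coordinates are handled 0-based half-open internally (converted
from GTF's 1-based inclusive at parse time) to match BAM block arithmetic.
Gene span, not transcript union, defines intron territory, so "intronic"
means "inside the gene but outside every annotated exon".

`stream_assignments()` bundles BAM records by read name (any sort order)
and classifies each pair by a first-match cascade: `unmapped` when no
usable mate remains (including all mates below `min_mapq`); `multimapping`
when the pair reports more than one alignment (NH tag when present,
otherwise record multiplicity) — unless `count_primary_multimappers` is
set, in which case only the primary alignment proceeds, reproducing the
zUMIs-compatible counting mode; then, from the union of both mates'
aligned blocks over the index: `no_feature` (no gene), `ambiguous` (≥ 2
genes), or `unique`. This is htseq-count's *union* overlap mode applied at
pair level: both mates vote jointly and a pair is never counted twice.
Secondary and supplementary records never vote.

**Exon dominance.** A unique pair is exonic if *any* overlapped base of its
gene is exonic, intronic only if every overlapped base is intronic. The
boundary-spanning case is genuinely underdetermined; exon dominance matches
the established exon/intron convention of comparable pipelines and is the
package's fixed choice (the index oracle tests pin it down).

**Strandedness** defaults to `none`: Smart-seq3 5' reads are not reliably
strand-informative after trimming. `forward`/`reverse` modes are available
for stranded protocols.

## Directional UMI correction

Per gene and region, raw UMI counts are corrected by merging 1-Hamming
neighbours under the frequency rule: *b* merges into *a* when
`count(a) >= 2 * count(b)` (at least twice as frequent). Processing order
is descending raw count with ascending lexicographic tie-break; a child
attaches to its highest-count eligible parent; merged UMIs are frozen —
they can neither be re-examined nor receive children — which is what
prevents chain merging from over-collapsing distinct molecules.
Eligibility always uses raw counts: a parent's absorbed mass never licenses
merges the raw data would not.

Two details of the inequality are configurable because either reading is
defensible: the package default is the literal `>= 2c`; `count_offset = 1`
gives `>= 2c - 1`, the inequality used by UMI-tools' directional method.
With a positive offset two singletons can merge, and to preserve the
no-chain invariant a UMI that has received children is then pinned as kept.
C ordering (`method = "radix"`) is used for all lexicographic tie-breaks so
results do not depend on the session locale.

Deduplicated molecules are `n_unique`; everything else is `n_duplicates`,
and `n_unique + n_duplicates` equals the raw UMI read count for every gene,
always — the conservation law behind the saturation identity
`dup / (dup + umi)`.

**Independent pools.** A gene's exonic and intronic UMI pools are corrected
and deduplicated separately; a UMI seen in both pools counts once in each.
Joint pooling would make the six tables non-conservative (a molecule could
vanish from both region tables); separate pooling keeps every table sum
interpretable. This is a deliberate choice where either convention could be
argued.

## The six matrices

Per cell: `umi_exon`, `umi_intron` (deduplicated molecules), `dup_exon`,
`dup_intron` (raw UMI reads minus molecules), `internal_exon`,
`internal_intron` (constructless pairs, one count each — without a UMI no
deduplication is possible). Cells are independent work units (one BAM = one
cell = one column, the plate-based convention; no in-BAM barcode parsing);
parallel execution merges results in declared input order, so outputs are
byte-identical for any worker count. Output is dense TSV plus sparse
MatrixMarket with axis sidecars and a JSON run report.

## The synthetic-data generator

`sim_config()` defines the study conditions; the defaults are the
conditions under which the package validates itself:

| parameter | default | meaning |
|---|---|---|
| `n_genes`, `n_cells` | 20, 5 | cohort of ~5,000 read pairs |
| `mean_molecules_per_gene` | 25 | Poisson molecules per gene per cell |
| `pcr_duplicate_rate` | 0.3 | expected duplicate read fraction |
| `anchor_error_rate` | 0.1 | reads given one anchor substitution |
| `anchor_shift_rate` | 0.05 | reads shifted 1 nt |
| `internal_read_fraction` | 0.3 | constructless share of genic pairs |
| `intronic_fraction` | 0.2 | molecules drawn from intron territory |
| `intergenic_fraction` | 0.05 | pairs from gene-free territory |
| `read_length` | 60 | cDNA length per mate |

PCR duplication draws each molecule's extra reads from a geometric
distribution with success probability `1 - pcr_duplicate_rate`; the
expected duplicate fraction then equals the configured rate, and (by a
delta-method calculation) its sampling standard deviation equals the
binomial standard error at the realized read count — which is exactly how
the tests bound it.

**Distinct UMIs.** By default (`umi_distinct = TRUE`) UMIs are
rejection-sampled to pairwise Hamming distance ≥ 2 within each gene ×
region pool. This makes the deduplicated count *identify* the true molecule
count, so end-to-end recovery can be asserted exactly rather than
approximately. With `umi_distinct = FALSE` UMIs are uniform over the 4⁸
space and collisions/adjacent pairs are a known, testable quantity recorded
in the truth table (the tests then assert conservation and
`measured ≤ truth` instead of equality).

**Overlap and category coverage.** With ≥ 4 genes the reference places one
gene pair overlapping by 300 bp. Molecule fragments are drawn only from
territory that belongs to a single gene, so ground truth stays exact;
dedicated reads drawn from the shared region (plus configurable unmapped
and NH=2 multimapped fractions) exercise the `ambiguous`, `unmapped` and
`multimapping` categories. The hermetic BAM writer places every pair at its
true locus with proper flags and simple `M` CIGARs — no aligner runs in the
tests.

What the generator does *not* emulate: quality-dependent error profiles,
indels, chimeras, expression-level biological structure, droplet barcodes.
Passing the end-to-end tests therefore demonstrates correctness of the
extraction/assignment/correction/accounting machinery under the stated read
model, not robustness to every artifact of real libraries.

## Problem sizes and numerical choices

The oracle suites are sized to run comfortably on one CPU: the anchor
scanner is checked exhaustively against a brute-force enumerator on every
two-letter read up to length 14 (~33,000 reads, against a two-letter toy
construct) plus 10,000 random four-letter reads under the default
construct; the corrector is checked exhaustively on all tallies of ≤ 3
distinct length-3 two-letter UMIs with counts 1–4 (~4,000 tallies) plus
1,000 random 8-nt tallies. The end-to-end cohort is 5 cells × 20 genes
(~5,000 pairs). These sizes are the package's own choices; all are
property-complete rather than sampled where enumeration is the point.

Degenerate inputs are defined behaviour: empty FASTQ/BAM inputs produce
empty outputs and zero tallies; a read shorter than the construct cannot
hit; a gene with no intron simply has empty intron territory; a cell whose
BAM fails to parse is skipped with a warning rather than aborting the
cohort; desynchronized FASTQ mates and malformed CIGARs are hard errors
naming the offending record.

## Known limitations

* BAM records are read per cell into memory and bundled by name; at plate
  scale (10⁵–10⁶ pairs per cell) this is cheap, but the implementation is
  not a streaming counter for very deep libraries.
* No indel-tolerant anchor matching, no quality-aware matching, no
  demultiplexing, no adapter trimming beyond the construct.
* Multimapper handling is primary-alignment counting or exclusion — no
  EM-style rescue.
* Exonic/intronic pools deduplicate independently (see above); analyses
  that want joint pooling should sum the raw tables and re-deduplicate
  upstream data.
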