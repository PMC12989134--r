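# umiquant

Error-tolerant UMI extraction and gene-level quantification for
Smart-seq3 single-cell RNA-seq libraries, from raw paired FASTQ to six
gene × cell count matrices.

## The problem

Smart-seq3 is a plate-based scRNA-seq protocol whose 5' reads carry a
molecular construct at the start of read 1:

```
[ anchor ATTGCGCAATG (11 nt) ][ UMI (8 nt) ][ GGG ][ cDNA ... ]
```

The UMI (unique molecular identifier) is a random barcode attached to each
transcript molecule before PCR, so duplicate reads of one molecule can be
collapsed into a single count. Position-based UMI detection — requiring the
anchor to sit exactly at read position 0 — silently discards reads in which
sequencing errors have mutated or shifted the anchor, and since non-UMI
reads are routinely dropped downstream, every missed UMI read is lost
signal. umiquant recovers those reads with *fuzzy matching*: bounded
Hamming-distance search of the anchor and trailing windows over a bounded
start-offset range.

The counting side streams aligned read pairs from one BAM per cell and
assigns each pair to exactly one category —

`unmapped` | `no_feature` | `multimapping` | `ambiguous` | `unique`

— by interval overlap with a GTF-derived index that distinguishes exon from
intron territory per gene (a pair is exonic if any overlapped base of its
gene is exonic; intronic reads are assigned directly from the gene span, no
transcriptome re-alignment). Per gene, UMIs are corrected by **directional
one-Hamming merging**: a UMI *b* merges into a neighbour *a* when
d(a, b) = 1 and count(a) ≥ 2·count(b), processing UMIs in descending count
order with merged UMIs frozen so no merge chains can over-collapse. The
result is six matrices, {UMI, internal, duplicate} × {exon, intron}, the
duplicate tables enabling per-cell saturation analysis.

A fully synthetic, ground-truthed simulator (toy genome + GTF, Smart-seq3
reads with injected anchor errors/shifts, PCR duplication, pre-made
alignments) makes the entire pipeline testable hermetically, with a known
answer for every matrix entry.

## Worked example

```r
library(umiquant)

# a 5-cell, 20-gene synthetic cohort with 10% anchor-substitution and
# 5% anchor-shift rates, 30% PCR duplication
cfg    <- sim_config(seed = 1)
cohort <- simulate_cohort(cfg)
cell   <- cohort$cells[[1]]

stats <- extract_umis(cell$fastq1, cell$fastq2,
                      "tagged_R1.fastq", "tagged_R2.fastq")
stats
#> # A tibble: 1 × 5
#>   n_pairs n_umi_strict n_umi_fuzzy n_internal n_rejected
#>     <int>        <int>       <int>      <int>      <int>
#> 1    1077          604          99        374          0
fuzzy_gain(stats)
#> [1] 0.140825
```

Of this cell's 703 UMI reads, strict (position-only) matching finds 604;
fuzzy matching rescues a further 99 — a 14.1% gain, the direct consequence
of the injected 10% substitution + 5% shift error rates. The tagged output
FASTQ carries each UMI in the read name (`<id>_<UMI>`), survives any
aligner, and is trimmed of the 22 nt construct.

```r
index <- build_feature_index(parse_gtf(cohort$ref$gtf))
mats  <- count_cells(vapply(cohort$cells, function(x) x$bam, ""),
                     index,
                     cell_ids = vapply(cohort$cells, function(x) x$cell_id, ""),
                     outdir = "counts")
glance(mats)
#> # A tibble: 5 × 6
#>   cell_id umi_molecules umi_duplicates internal_reads umi_library_size
#>   <chr>           <int>          <int>          <int>            <int>
#> 1 cell01            475            228            301              703
#> 2 cell02            472            199            288              671
#> 3 cell03            532            228            326              760
#> 4 cell04            481            242            310              723
#> 5 cell05            483            227            304              710
#> # ℹ 1 more variable: duplicate_fraction <dbl>
```

cell01's 703 raw UMI read pairs collapse to 475 distinct molecules and 228
PCR duplicates (duplicate fraction 0.32, matching the simulated 30% PCR
rate); `counts/` now holds the six matrices as TSV + MatrixMarket plus a
JSON run report. `autoplot(mats)` draws the per-cell saturation plot
(duplicate fraction vs. UMI library size), and `tidy(mats)` returns the
long gene × cell × matrix table. Shell wrappers for the two pipeline stages
and the simulator live in `inst/scripts/` (`umiextract.R`, `umicount.R`,
`umisim.R`).

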