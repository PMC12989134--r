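# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# error-free 5-cell x 20-gene cohort: the ground-truth recovery conditions
clean_cohort <- function() {
  if (is.null(.fixtures$clean)) {
    cfg <- sim_config(seed = 20260926, anchor_error_rate = 0,
                      anchor_shift_rate = 0)
    .fixtures$clean <- list(cfg = cfg, coh = simulate_cohort(cfg))
  }
  .fixtures$clean
}

# noisy 2-cell cohort exercising every assignment category
categories_cohort <- function() {
  if (is.null(.fixtures$cats)) {
    cfg <- sim_config(seed = 424243, n_genes = 8, n_cells = 2,
                      mean_molecules_per_gene = 40,
                      unmapped_rate = 0.05, multimap_rate = 0.05,
                      ambiguous_fraction = 0.05, intergenic_fraction = 0.08)
    .fixtures$cats <- list(cfg = cfg, coh = simulate_cohort(cfg))
  }
  .fixtures$cats
}

# hand-written two-gene annotation on one toy chromosome:
#   GA: span 0..1000, exons [0,200) and [800,1000)   (strand +)
#   GB: span 2000..2600, exons [2000,2200) and [2400,2600)  (strand -)
toy_gtf <- function(path = tempfile(fileext = ".gtf")) {
  writeLines(c(
    'chrT\ttest\tgene\t1\t1000\t.\t+\t.\tgene_id "GA";',
    'chrT\ttest\texon\t1\t200\t.\t+\t.\tgene_id "GA"; transcript_id "GA.1";',
    'chrT\ttest\texon\t801\t1000\t.\t+\t.\tgene_id "GA"; transcript_id "GA.1";',
    'chrT\ttest\tgene\t2001\t2600\t.\t-\t.\tgene_id "GB";',
    'chrT\ttest\texon\t2001\t2200\t.\t-\t.\tgene_id "GB"; transcript_id "GB.1";',
    'chrT\ttest\texon\t2401\t2600\t.\t-\t.\tgene_id "GB"; transcript_id "GB.1";'),
    path)
  path
}

toy_index <- function() {
  if (is.null(.fixtures$toy_index)) {
    .fixtures$toy_index <- build_feature_index(parse_gtf(toy_gtf()))
  }
  .fixtures$toy_index
}

# write a SAM file over chrT (len 5000); records is a list of character
# vectors already laid out as SAM fields
toy_sam <- function(records, path = tempfile(fileext = ".sam")) {
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chrT\tLN:5000", records),
             path)
  path
}

# one aligned SAM record; pos is 1-based
sam_rec <- function(qname, flag, pos, cigar = "50M", rname = "chrT",
                    mapq = 60L, nh = NULL) {
  base <- paste(qname, flag, rname, pos, mapq, cigar, "*", 0, 0, "*", "*",
                sep = "\t")
  if (!is.null(nh)) base <- paste0(base, sprintf("\tNH:i:%d", nh))
  base
}

sam_unmapped_pair <- function(qname) {
  c(paste(qname, 77, "*", 0, 0, "*", "*", 0, 0, "*", "*", sep = "\t"),
    paste(qname, 141, "*", 0, 0, "*", "*", 0, 0, "*", "*", sep = "\t"))
}

# a mapped proper pair: mate1 fwd at pos1, mate2 rev at pos2 (1-based)
sam_pair <- function(qname, pos1, pos2, cigar = "50M", nh = NULL) {
  c(sam_rec(qname, 99L, pos1, cigar, nh = nh),
    sam_rec(qname, 147L, pos2, cigar, nh = nh))
}

# write paired FASTQ files from parallel id/seq vectors (qual all "I")
write_fastq_pair <- function(ids, seq1, seq2,
                             f1 = tempfile(fileext = ".fastq"),
                             f2 = tempfile(fileext = ".fastq")) {
  w <- function(path, ids, seqs) {
    writeLines(as.vector(rbind(paste0("@", ids), seqs, "+",
                               strrep("I", nchar(seqs)))), path)
  }
  w(f1, ids, seq1)
  w(f2, ids, seq2)
  c(f1, f2)
}

# random nucleotide string helper
rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

DEFAULT_CONSTRUCT <- function(umi, cdna, cfg = extraction_config()) {
  paste0(cfg$anchor, umi, cfg$trailing, cdna)
}
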