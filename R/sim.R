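#' Configuration for the synthetic Smart-seq3 data generator
#'
#' Defines a fully synthetic study: a toy genome and annotation, per-cell
#' read sets with the Smart-seq3 construct (anchor + UMI + trailing + cDNA
#' on read 1 of UMI reads; plain cDNA on internal reads), injected anchor
#' substitutions and shifts, PCR duplication, and reads from exonic,
#' intronic, intergenic and gene-overlap loci. Every emitted read pair is
#' traceable to exactly one row of the ground-truth table, so end-to-end
#' counting has a known answer.
#'
#' @param seed Integer seed; the same seed yields byte-identical outputs.
#' @param n_genes Number of genes on the toy chromosome; when `>= 4` one
#'   gene pair is placed overlapping to exercise the `ambiguous` category.
#' @param exons_per_gene Exons per gene.
#' @param n_cells Number of cells in a cohort.
#' @param mean_molecules_per_gene Poisson mean of distinct molecules per
#'   gene per cell.
#' @param umi_length UMI length (nt).
#' @param pcr_duplicate_rate Expected fraction of UMI read pairs that are
#'   PCR re-reads of an already-seen molecule; per molecule the number of
#'   extra reads is geometric with success probability
#'   `1 - pcr_duplicate_rate`.
#' @param anchor_error_rate Per UMI read, probability of exactly one random
#'   substitution inside the anchor.
#' @param anchor_shift_rate Per UMI read, probability of a 1 nt shift (one
#'   random base prepended before the anchor).
#' @param internal_read_fraction Fraction of genic read pairs that are
#'   internal (constructless) reads.
#' @param intronic_fraction Fraction of genic fragments drawn from intron
#'   rather than exon territory.
#' @param intergenic_fraction Fraction of all read pairs drawn from
#'   intergenic territory.
#' @param ambiguous_fraction Fraction of read pairs drawn from the shared
#'   region of the overlapping gene pair (0 when no overlap exists).
#' @param unmapped_rate Per pair, probability of being written unmapped in
#'   the simulated BAM.
#' @param multimap_rate Per pair, probability of being written with a
#'   secondary alignment and `NH = 2`.
#' @param read_length cDNA length of each mate (nt).
#' @param umi_distinct When `TRUE` (default), UMIs within one gene x region
#'   pool are rejection-sampled to pairwise Hamming distance >= 2, so the
#'   deduplicated molecule count identifies the true molecule count
#'   exactly. When `FALSE`, UMIs are uniform over the 4^umi_length space
#'   and collisions are a known quantity recorded in the truth table.
#' @param extraction The [extraction_config()] whose construct the reads
#'   carry.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L, n_genes = 20L, exons_per_gene = 3L,
                       n_cells = 5L, mean_molecules_per_gene = 25,
                       umi_length = 8L, pcr_duplicate_rate = 0.3,
                       anchor_error_rate = 0.1, anchor_shift_rate = 0.05,
                       internal_read_fraction = 0.3,
                       intronic_fraction = 0.2, intergenic_fraction = 0.05,
                       ambiguous_fraction = 0.02, unmapped_rate = 0,
                       multimap_rate = 0, read_length = 60L,
                       umi_distinct = TRUE,
                       extraction = extraction_config(umi_length = umi_length)) {
  probs <- c(pcr_duplicate_rate, anchor_error_rate, anchor_shift_rate,
             internal_read_fraction, intronic_fraction, intergenic_fraction,
             ambiguous_fraction, unmapped_rate, multimap_rate)
  if (any(probs < 0 | probs > 1)) abort("all rates must lie in [0, 1]")
  if (extraction$umi_length != umi_length) {
    abort("umi_length must match the extraction config")
  }
  structure(
    list(seed = as.integer(seed), n_genes = as.integer(n_genes),
         exons_per_gene = as.integer(exons_per_gene),
         n_cells = as.integer(n_cells),
         mean_molecules_per_gene = mean_molecules_per_gene,
         umi_length = as.integer(umi_length),
         pcr_duplicate_rate = pcr_duplicate_rate,
         anchor_error_rate = anchor_error_rate,
         anchor_shift_rate = anchor_shift_rate,
         internal_read_fraction = internal_read_fraction,
         intronic_fraction = intronic_fraction,
         intergenic_fraction = intergenic_fraction,
         ambiguous_fraction = ambiguous_fraction,
         unmapped_rate = unmapped_rate, multimap_rate = multimap_rate,
         read_length = as.integer(read_length),
         umi_distinct = isTRUE(umi_distinct),
         extraction = extraction),
    class = "sim_config")
}

.SIM_CHROM <- "chrS"

#' Simulate a toy genome and GTF annotation
#'
#' Multi-exon genes laid out along one chromosome with intergenic gaps;
#' when `n_genes >= 4`, the fourth gene's first exon overlaps the third
#' gene's last exon (a 300 bp shared region) so ambiguous assignments are
#' producible. The GTF parses under [parse_gtf()] with no errors.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory for `genome.fa` and `annotation.gtf`.
#' @return A list: `fasta`, `gtf` (paths), `genome` (DNAStringSet),
#'   `models` (gene-model tibble as from [parse_gtf()]), `overlap` (tibble
#'   with the shared region, or `NULL`), `intergenic` (tibble of gap
#'   intervals, 0-based half-open).
#' @export
simulate_reference <- function(cfg, dir = tempfile("simref")) {
  set.seed(cfg$seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  overlap_w <- 300L

  rows <- vector("list", cfg$n_genes)
  overlap <- NULL
  cursor <- 500L
  prev_end <- NA_integer_
  for (g in seq_len(cfg$n_genes)) {
    if (g == 4L && cfg$n_genes >= 4L) {
      # pull this gene back so its first exon overlaps the previous gene
      cursor <- prev_end - overlap_w
      overlap <- tibble(gene_a = rows[[3L]]$gene_id, gene_b = sprintf("G%02d", g),
                        start = cursor, end = prev_end)
    }
    ex_len <- sample(400:500, cfg$exons_per_gene, replace = TRUE)
    in_len <- if (cfg$exons_per_gene > 1L)
      sample(200:300, cfg$exons_per_gene - 1L, replace = TRUE) else integer(0)
    starts <- cursor + cumsum(c(0L, head(ex_len, -1L) + in_len))
    ends <- starts + ex_len
    rows[[g]] <- tibble(
      gene_id = sprintf("G%02d", g),
      chrom = .SIM_CHROM,
      strand = if (g %% 2L == 1L) "+" else "-",
      start = starts[1L],
      end = ends[length(ends)],
      exons = list(tibble(start = starts, end = ends)))
    prev_end <- ends[length(ends)]
    cursor <- prev_end + sample(400:600, 1L)
  }
  models <- bind_rows(rows)

  glen <- max(models$end) + 500L
  genome <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                  collapse = "")
  genome_set <- Biostrings::DNAStringSet(setNames(genome, .SIM_CHROM))

  fasta <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(genome_set, fasta)
  gtf <- file.path(dir, "annotation.gtf")
  write_gtf(models, gtf)

  spans <- IRanges::reduce(IRanges::IRanges(models$start + 1L, models$end))
  gaps <- BiocGenerics::setdiff(IRanges::IRanges(1L, glen), spans)
  intergenic <- tibble(start = IRanges::start(gaps) - 1L,
                       end = IRanges::end(gaps))

  list(fasta = fasta, gtf = gtf, genome = genome_set, models = models,
       overlap = overlap, intergenic = intergenic)
}

# territory of each gene x region, minus any other gene's span, as 0-based
# half-open tibbles: list(gene_id -> list(exon = tbl, intron = tbl))
.allowed_territory <- function(models) {
  spans <- IRanges::IRanges(models$start + 1L, models$end)
  out <- vector("list", nrow(models))
  names(out) <- models$gene_id
  for (i in seq_len(nrow(models))) {
    others <- spans[-i]
    ex <- IRanges::IRanges(models$exons[[i]]$start + 1L, models$exons[[i]]$end)
    intr <- BiocGenerics::setdiff(spans[i], ex)
    ex_ok <- BiocGenerics::setdiff(ex, others)
    in_ok <- BiocGenerics::setdiff(intr, others)
    out[[i]] <- list(
      exon = tibble(start = IRanges::start(ex_ok) - 1L,
                    end = IRanges::end(ex_ok)),
      intron = tibble(start = IRanges::start(in_ok) - 1L,
                      end = IRanges::end(in_ok)))
  }
  out
}

# sample one fragment of length frag_len fully inside one of the intervals
# (0-based half-open); NULL if nothing fits
.sample_fragment <- function(intervals, frag_len) {
  w <- intervals$end - intervals$start
  ok <- which(w >= frag_len)
  if (length(ok) == 0L) return(NULL)
  slack <- w[ok] - frag_len + 1L
  i <- if (length(ok) == 1L) ok else
    ok[sample.int(length(ok), 1L, prob = slack)]
  s <- intervals$start[i] + sample.int(w[i] - frag_len + 1L, 1L) - 1L
  c(start = s, end = s + frag_len)
}

# draw a UMI; with distinct = TRUE, rejection-sample to pairwise Hamming
# distance >= 2 against the pool
.draw_umi <- function(len, pool, distinct) {
  repeat {
    u <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    if (!distinct) return(u)
    if (length(pool) == 0L ||
        all(vapply(pool, function(p) hamming(p, u), integer(1)) >= 2L)) {
      return(u)
    }
  }
}

# mutate the anchor with exactly one substitution at a random position
.mutate_anchor <- function(anchor) {
  pos <- sample.int(nchar(anchor), 1L)
  old <- substr(anchor, pos, pos)
  new <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
  paste0(substr(anchor, 1L, pos - 1L), new,
         substr(anchor, pos + 1L, nchar(anchor)))
}

#' Simulate one cell's Smart-seq3 FASTQ pair with ground truth
#'
#' Draws molecules per gene, assigns each to exon or intron territory,
#' gives each a UMI and a genomic fragment, re-reads molecules according
#' to the PCR duplication model, adds internal, intergenic and (when the
#' reference has an overlapping gene pair) ambiguous read pairs, injects
#' anchor substitutions and shifts into UMI reads, and writes the pair of
#' FASTQ files in a seed-determined shuffled order.
#'
#' @param cfg A [sim_config()].
#' @param ref A [simulate_reference()] result.
#' @param cell Cell number (1-based); fixes the per-cell RNG substream at
#'   `cfg$seed + 131 * cell`.
#' @param dir Output directory.
#' @return A list: `cell_id`, `fastq1`, `fastq2` (paths), `truth` (tibble
#'   with one row per emitted read pair: identifiers, origin gene/region,
#'   molecule id, true UMI, duplicate/error/shift flags, alignment
#'   coordinates and unmapped/multimap flags for [simulate_alignments()]).
#' @export
simulate_cell_reads <- function(cfg, ref, cell = 1L, dir = tempfile("simcell")) {
  set.seed(cfg$seed + 131L * as.integer(cell))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cell_id <- sprintf("cell%02d", as.integer(cell))
  territory <- .allowed_territory(ref$models)
  rl <- cfg$read_length
  ex_cfg <- cfg$extraction

  frag_of <- function(intervals) {
    frag_len <- rl * 2L + sample(0:40, 1L)
    fr <- .sample_fragment(intervals, frag_len)
    if (is.null(fr)) fr <- .sample_fragment(intervals, rl)  # overlapping mates
    fr
  }

  # --- molecules: one row per distinct molecule, then expand by PCR ---
  m_per_gene <- rpois(nrow(ref$models), cfg$mean_molecules_per_gene)
  n_mol <- sum(m_per_gene)
  mol_gene <- character(n_mol); mol_region <- character(n_mol)
  mol_umi <- character(n_mol); mol_id <- character(n_mol)
  mol_s1 <- integer(n_mol); mol_s2 <- integer(n_mol)
  keep <- logical(n_mol)
  i <- 0L
  for (gi in seq_len(nrow(ref$models))) {
    gene <- ref$models$gene_id[gi]
    if (m_per_gene[gi] == 0L) next
    pools <- list(exon = character(0), intron = character(0))
    for (j in seq_len(m_per_gene[gi])) {
      i <- i + 1L
      region <- if (runif(1) < cfg$intronic_fraction &&
                    nrow(territory[[gene]]$intron) > 0L) "intron" else "exon"
      fr <- frag_of(territory[[gene]][[region]])
      if (is.null(fr)) next
      umi <- .draw_umi(cfg$umi_length, pools[[region]], cfg$umi_distinct)
      pools[[region]] <- c(pools[[region]], umi)
      keep[i] <- TRUE
      mol_gene[i] <- gene; mol_region[i] <- region; mol_umi[i] <- umi
      mol_id[i] <- sprintf("%s:%s:m%04d", cell_id, gene, j)
      mol_s1[i] <- fr[["start"]]; mol_s2[i] <- fr[["end"]] - rl
    }
  }
  ix <- which(keep)
  n_reads <- 1L + rgeom(length(ix), 1 - cfg$pcr_duplicate_rate)
  rix <- rep(ix, n_reads)
  umi_truth <- tibble(
    read_type = "umi", gene_id = mol_gene[rix], region = mol_region[rix],
    molecule_id = mol_id[rix], umi = mol_umi[rix],
    duplicate = duplicated(rix),
    start1 = mol_s1[rix], start2 = mol_s2[rix])
  n_umi_pairs <- nrow(umi_truth)

  # --- internal (constructless) genic pairs ---
  f <- cfg$internal_read_fraction
  n_internal <- if (f > 0) round(f / (1 - f) * n_umi_pairs) else 0L
  sample_genic <- function(n, type) {
    if (n == 0L) return(NULL)
    out <- vector("list", n)
    for (j in seq_len(n)) {
      gene <- sample(ref$models$gene_id, 1L)
      region <- if (runif(1) < cfg$intronic_fraction &&
                    nrow(territory[[gene]]$intron) > 0L) "intron" else "exon"
      fr <- frag_of(territory[[gene]][[region]])
      if (is.null(fr)) next
      out[[j]] <- c(gene = gene, region = region,
                    start1 = fr[["start"]], start2 = fr[["end"]] - rl)
    }
    out <- out[!vapply(out, is.null, logical(1))]
    if (length(out) == 0L) return(NULL)
    mat <- do.call(rbind, out)
    tibble(read_type = type, gene_id = mat[, "gene"],
           region = mat[, "region"], molecule_id = NA_character_,
           umi = NA_character_, duplicate = FALSE,
           start1 = as.integer(mat[, "start1"]),
           start2 = as.integer(mat[, "start2"]))
  }
  internal_truth <- sample_genic(n_internal, "internal")

  n_genic <- n_umi_pairs + n_internal

  # --- intergenic and gene-overlap ("ambiguous") pairs ---
  sample_region <- function(n, intervals, type) {
    if (n == 0L) return(NULL)
    frs <- lapply(seq_len(n), function(j) frag_of(intervals))
    frs <- frs[!vapply(frs, is.null, logical(1))]
    if (length(frs) == 0L) return(NULL)
    mat <- do.call(rbind, frs)
    tibble(read_type = type, gene_id = NA_character_,
           region = NA_character_, molecule_id = NA_character_,
           umi = NA_character_, duplicate = FALSE,
           start1 = as.integer(mat[, "start"]),
           start2 = as.integer(mat[, "end"]) - rl)
  }
  fi <- cfg$intergenic_fraction
  inter_truth <- sample_region(
    if (fi > 0) round(fi / (1 - fi) * n_genic) else 0L,
    ref$intergenic, "intergenic")
  fa <- cfg$ambiguous_fraction
  amb_truth <- if (fa > 0 && !is.null(ref$overlap)) {
    sample_region(round(fa / (1 - fa) * n_genic),
                  tibble(start = ref$overlap$start, end = ref$overlap$end),
                  "ambiguous")
  } else NULL

  truth <- bind_rows(umi_truth, internal_truth, inter_truth, amb_truth)
  n <- nrow(truth)
  if (n == 0L) {
    truth <- tibble(
      cell_id = character(), read_id = character(), read_type = character(),
      gene_id = character(), region = character(),
      molecule_id = character(), umi = character(), duplicate = logical(),
      anchor_error = logical(), shifted = logical(), aligned = logical(),
      multimap = logical(), chrom = character(), start1 = integer(),
      start2 = integer(), read_length = integer())
    fastq1 <- file.path(dir, paste0(cell_id, "_R1.fastq"))
    fastq2 <- file.path(dir, paste0(cell_id, "_R2.fastq"))
    .sim_write_fastq(fastq1, character(0), character(0))
    .sim_write_fastq(fastq2, character(0), character(0))
    return(list(cell_id = cell_id, fastq1 = fastq1, fastq2 = fastq2,
                truth = truth))
  }
  truth <- truth |>
    mutate(
      cell_id = cell_id,
      read_id = sprintf("%s:r%06d", cell_id, seq_len(n)),
      chrom = .SIM_CHROM,
      read_length = rl,
      anchor_error = .data$read_type == "umi" &
        runif(n) < cfg$anchor_error_rate,
      shifted = .data$read_type == "umi" & runif(n) < cfg$anchor_shift_rate,
      aligned = runif(n) >= cfg$unmapped_rate,
      multimap = .data$aligned & runif(n) < cfg$multimap_rate) |>
    select("cell_id", "read_id", "read_type", "gene_id", "region",
           "molecule_id", "umi", "duplicate", "anchor_error", "shifted",
           "aligned", "multimap", "chrom", "start1", "start2", "read_length")

  # --- FASTQ emission in shuffled order ---
  genome <- as.character(ref$genome[[1L]])
  cdna1 <- substr(rep(genome, n), truth$start1 + 1L, truth$start1 + rl)
  cdna2_fwd <- substr(rep(genome, n), truth$start2 + 1L, truth$start2 + rl)
  cdna2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(cdna2_fwd)))

  anchors <- rep(ex_cfg$anchor, n)
  err <- which(truth$anchor_error)
  for (i in err) anchors[i] <- .mutate_anchor(ex_cfg$anchor)
  prefix <- ifelse(truth$shifted,
                   sample(c("A", "C", "G", "T"), n, replace = TRUE), "")
  is_umi <- truth$read_type == "umi"
  seq1 <- ifelse(is_umi,
                 paste0(prefix, anchors, truth$umi, ex_cfg$trailing, cdna1),
                 cdna1)

  ord <- sample.int(n)
  fastq1 <- file.path(dir, paste0(cell_id, "_R1.fastq"))
  fastq2 <- file.path(dir, paste0(cell_id, "_R2.fastq"))
  .sim_write_fastq(fastq1, truth$read_id[ord], seq1[ord])
  .sim_write_fastq(fastq2, truth$read_id[ord], cdna2[ord])

  list(cell_id = cell_id, fastq1 = fastq1, fastq2 = fastq2, truth = truth)
}

.sim_write_fastq <- function(path, ids, seqs) {
  if (file.exists(path)) unlink(path)
  obj <- ShortRead::ShortReadQ(
    sread = Biostrings::DNAStringSet(seqs),
    quality = Biostrings::BStringSet(strrep("I", nchar(seqs))),
    id = Biostrings::BStringSet(ids))
  ShortRead::writeFastq(obj, path, mode = "w",
                        compress = grepl("\\.gz$", path))
}

#' Write a cell's truth table as a coordinate-sorted BAM
#'
#' Bypasses the aligner for hermetic tests: every pair is written at its
#' true locus with proper flags and `<read_length>M` CIGARs, read names
#' carrying the `"_<UMI>"` tag exactly as post-extraction alignment would.
#' Pairs flagged unmapped in the truth are written as unmapped records;
#' pairs flagged multimapping get `NH:i:2` plus a secondary alignment at a
#' decoy intergenic locus, exercising every assignment category.
#'
#' @param truth Truth tibble from [simulate_cell_reads()].
#' @param ref The [simulate_reference()] result.
#' @param path Output BAM path (`.bam`).
#' @return The BAM path.
#' @export
simulate_alignments <- function(truth, ref, path) {
  stopifnot(grepl("\\.bam$", path))
  genome <- as.character(ref$genome[[1L]])
  glen <- nchar(genome)
  decoy <- ref$intergenic$start[1L] + 10L
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", .SIM_CHROM, glen))

  n <- nrow(truth)
  lines <- character(0)
  if (n > 0L) {
    rl <- truth$read_length
    qname <- ifelse(truth$read_type == "umi",
                    paste0(truth$read_id, "_", truth$umi), truth$read_id)
    s1 <- substr(rep(genome, n), truth$start1 + 1L, truth$start1 + rl)
    s2 <- substr(rep(genome, n), truth$start2 + 1L, truth$start2 + rl)
    q <- strrep("I", rl)
    p1 <- truth$start1 + 1L
    p2 <- truth$start2 + 1L
    tlen <- truth$start2 + rl - truth$start1
    cig <- sprintf("%dM", rl)
    nh <- ifelse(truth$multimap, "NH:i:2", "NH:i:1")

    a1 <- paste(qname, 99L, truth$chrom, p1, 255L, cig, "=", p2, tlen,
                s1, q, nh, sep = "\t")
    a2 <- paste(qname, 147L, truth$chrom, p2, 255L, cig, "=", p1, -tlen,
                s2, q, nh, sep = "\t")
    u1 <- paste(qname, 77L, "*", 0L, 0L, "*", "*", 0L, 0L, s1, q, sep = "\t")
    u2 <- paste(qname, 141L, "*", 0L, 0L, "*", "*", 0L, 0L, s2, q, sep = "\t")
    al <- truth$aligned
    lines <- as.vector(rbind(ifelse(al, a1, u1), ifelse(al, a2, u2)))

    mm <- which(truth$multimap & al)
    if (length(mm)) {
      dp <- pmin(decoy, glen - rl[mm] - 1L) + 1L
      lines <- c(lines,
        paste(qname[mm], 355L, truth$chrom[mm], dp, 0L, cig[mm], "=", dp,
              0L, "*", "*", "NH:i:2", sep = "\t"),
        paste(qname[mm], 403L, truth$chrom[mm], dp, 0L, cig[mm], "=", dp,
              0L, "*", "*", "NH:i:2", sep = "\t"))
    }
  }

  sam <- sub("\\.bam$", ".sam", path)
  writeLines(c(hdr, lines), sam)
  tmp <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  sorted <- Rsamtools::sortBam(tmp, sub("\\.bam$", "", path))
  unlink(c(sam, tmp))
  sorted
}

#' Simulate a full cohort: reference, per-cell FASTQ, truth and BAM
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (reference plus one subdirectory per cell).
#' @return A list: `ref`, `cells` (list per cell with `cell_id`, `fastq1`,
#'   `fastq2`, `truth`, `bam`), `truth` (all cells bound together).
#' @export
simulate_cohort <- function(cfg, dir = tempfile("simcohort")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- simulate_reference(cfg, file.path(dir, "ref"))
  cells <- lapply(seq_len(cfg$n_cells), function(ci) {
    cell <- simulate_cell_reads(cfg, ref, ci, file.path(dir, "cells"))
    cell$bam <- simulate_alignments(
      cell$truth, ref, file.path(dir, "cells", paste0(cell$cell_id, ".bam")))
    cell
  })
  list(ref = ref, cells = cells,
       truth = bind_rows(lapply(cells, function(x) x$truth)))
}

#' Ground-truth molecule table
#'
#' Distinct true molecules per cell, gene and region, restricted to read
#' pairs the pipeline can see (aligned, and — unless primary-multimapper
#' counting is assumed — not multimapping). This is the expected value of
#' the `umi_exon` / `umi_intron` matrices on error-free simulations with
#' distinct UMIs.
#'
#' @param truth A truth tibble (one or more cells).
#' @param include_multimapped Count molecules whose every read is
#'   multimapping (relevant with `count_primary_multimappers = TRUE`).
#' @return A tibble: `cell_id`, `gene_id`, `region`, `n_molecules`,
#'   `n_reads` (raw UMI read pairs).
#' @export
truth_molecule_table <- function(truth, include_multimapped = FALSE) {
  truth |>
    filter(.data$read_type == "umi", .data$aligned,
           include_multimapped | !.data$multimap) |>
    group_by(.data$cell_id, .data$gene_id, .data$region) |>
    summarise(n_molecules = dplyr::n_distinct(.data$molecule_id),
              n_reads = dplyr::n(), .groups = "drop")
}
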