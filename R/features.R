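#' Parse a GTF annotation into gene models
#'
#' Reads gene- and exon-level GTF features (Ensembl/GENCODE attribute
#' dialect) and returns one model per `gene_id`: the gene span, and the
#' merged union of its exons across all transcripts. Coordinates are
#' converted from GTF 1-based inclusive to 0-based half-open, the
#' convention used throughout the package (matching BAM block arithmetic).
#' When no `gene` feature line is present for a gene, its span is the hull
#' of its exons. Chromosome names are passed through verbatim.
#'
#' @param gtf Path to a GTF file (plain or gzip).
#' @return A tibble of gene models ordered by first appearance in the GTF:
#'   `gene_id`, `chrom`, `strand` (`+`, `-` or `.`), `start`, `end`
#'   (0-based half-open span), and `exons`, a list-column of tibbles with
#'   merged, disjoint, sorted `start`/`end` intervals.
#' @export
parse_gtf <- function(gtf) {
  gr <- rtracklayer::import(gtf, format = "gtf")
  if (length(gr) == 0L) abort("GTF contains no features")
  type <- as.character(gr$type)
  exon <- gr[type == "exon"]
  if (length(exon) == 0L) abort("GTF contains no exon features")
  if (is.null(exon$gene_id) || anyNA(exon$gene_id)) {
    i <- if (is.null(exon$gene_id)) 1L else which(is.na(exon$gene_id))[1L]
    abort(sprintf(
      "exon feature %d (%s:%d-%d) lacks a gene_id attribute",
      i, as.character(GenomeInfoDb::seqnames(exon))[i],
      GenomicRanges::start(exon)[i], GenomicRanges::end(exon)[i]))
  }
  gene <- gr[type == "gene"]

  # order of first appearance over all features defines the gene axis
  all_ids <- gr$gene_id
  gene_order <- unique(all_ids[!is.na(all_ids) & type %in% c("gene", "exon")])

  exon_tbl <- tibble(
    gene_id = exon$gene_id,
    chrom = as.character(GenomeInfoDb::seqnames(exon)),
    strand = as.character(BiocGenerics::strand(exon)),
    start = GenomicRanges::start(exon) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(exon)
  )
  gene_tbl <- if (length(gene) && !is.null(gene$gene_id)) {
    tibble(gene_id = gene$gene_id,
           chrom = as.character(GenomeInfoDb::seqnames(gene)),
           strand = as.character(BiocGenerics::strand(gene)),
           start = GenomicRanges::start(gene) - 1L,
           end = GenomicRanges::end(gene))
  } else {
    tibble(gene_id = character(), chrom = character(), strand = character(),
           start = integer(), end = integer())
  }

  models <- exon_tbl |>
    group_by(.data$gene_id) |>
    summarise(
      chrom = first(.data$chrom),
      strand = first(.data$strand),
      exons = list(.merge_intervals(.data$start, .data$end)),
      hull_start = min(.data$start),
      hull_end = max(.data$end),
      .groups = "drop"
    ) |>
    left_join(gene_tbl |> select("gene_id", g_start = "start", g_end = "end"),
              by = "gene_id") |>
    mutate(
      start = dplyr::coalesce(.data$g_start, .data$hull_start),
      end = dplyr::coalesce(.data$g_end, .data$hull_end),
      strand = ifelse(.data$strand == "*", ".", .data$strand)
    ) |>
    select("gene_id", "chrom", "strand", "start", "end", "exons")

  bad_span <- purrr::map2_lgl(models$exons, seq_len(nrow(models)), function(e, i) {
    any(e$start < models$start[i]) || any(e$end > models$end[i])
  })
  if (any(bad_span)) {
    abort(sprintf("gene %s has exons outside its declared span",
                  models$gene_id[which(bad_span)[1L]]))
  }
  models[match(gene_order, models$gene_id), , drop = FALSE]
}

# merge possibly-overlapping 0-based half-open intervals into a disjoint,
# sorted union
.merge_intervals <- function(start, end) {
  ir <- IRanges::reduce(IRanges::IRanges(start + 1L, end))
  tibble(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}

#' Serialize gene models back to GTF
#'
#' Writes one `gene` line per model and one `exon` line per merged exon
#' interval, in the Ensembl attribute dialect. Round-trips with
#' [parse_gtf()] on its own output.
#'
#' @param models Gene-model tibble as returned by [parse_gtf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  lines <- character(0)
  for (i in seq_len(nrow(models))) {
    m <- models[i, ]
    attr_str <- sprintf('gene_id "%s";', m$gene_id)
    strand <- if (m$strand == ".") "." else m$strand
    lines <- c(lines, paste(
      m$chrom, "umiquant", "gene", m$start + 1L, m$end, ".", strand, ".",
      attr_str, sep = "\t"))
    ex <- m$exons[[1L]]
    tattr <- sprintf('gene_id "%s"; transcript_id "%s.t1";',
                     m$gene_id, m$gene_id)
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, paste(
        m$chrom, "umiquant", "exon", ex$start[j] + 1L, ex$end[j], ".",
        strand, ".", tattr, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Build a genome-wide exon/intron interval index from gene models
#'
#' For every gene, exon territory is the merged exon union and intron
#' territory is the gene span minus that union; no position carries both
#' labels for the same gene. The index supports overlap queries via
#' [query_blocks()] and backs read-pair classification.
#'
#' @param models Gene-model tibble from [parse_gtf()].
#' @return An object of class `"feature_index"`.
#' @export
build_feature_index <- function(models) {
  n_ex <- vapply(models$exons, nrow, integer(1))
  ex_gr <- GenomicRanges::GRanges(
    rep(models$chrom, n_ex),
    IRanges::IRanges(
      unlist(lapply(models$exons, function(e) e$start + 1L), use.names = FALSE),
      unlist(lapply(models$exons, function(e) e$end), use.names = FALSE)),
    gene_id = rep(models$gene_id, n_ex),
    label = "exon",
    gene_strand = rep(models$strand, n_ex))

  intr <- purrr::pmap(
    list(models$chrom, models$start, models$end, models$exons,
         models$gene_id, models$strand),
    function(chrom, start, end, exons, gene_id, strand) {
      span <- IRanges::IRanges(start + 1L, end)
      gaps <- BiocGenerics::setdiff(
        span, IRanges::IRanges(exons$start + 1L, exons$end))
      if (length(gaps) == 0L) return(NULL)
      GenomicRanges::GRanges(chrom, gaps, gene_id = gene_id, label = "intron",
                             gene_strand = strand)
    })
  intr <- intr[!vapply(intr, is.null, logical(1))]
  gr <- c(ex_gr, if (length(intr)) do.call(c, intr) else GenomicRanges::GRanges())

  structure(
    list(gr = gr, genes = models$gene_id,
         gene_strand = setNames(models$strand, models$gene_id),
         chroms = unique(models$chrom),
         warned = new.env(parent = emptyenv())),
    class = "feature_index")
}

#' @export
print.feature_index <- function(x, ...) {
  cat(sprintf("feature_index: %d genes, %d intervals on %d chromosome(s)\n",
              length(x$genes), length(x$gr), length(x$chroms)))
  invisible(x)
}

#' Query the feature index with the aligned blocks of a read (pair)
#'
#' Returns the genes overlapped by any position of any block, with the
#' exon-dominance rule: a gene is reported as `exon` if any overlapped
#' position is exonic for it, and as `intron` only when every overlapped
#' position of that gene is intronic. Blocks on an unknown chromosome
#' contribute nothing (warned once per chromosome per index).
#'
#' @param index A [build_feature_index()] object.
#' @param chrom Chromosome name of the blocks.
#' @param blocks A data frame/tibble with 0-based half-open `start`, `end`
#'   columns — the aligned segments of a read, gaps excluded.
#' @return A tibble with columns `gene_id` and `label` (`"exon"` or
#'   `"intron"`), zero rows for intergenic queries.
#' @export
query_blocks <- function(index, chrom, blocks) {
  stopifnot(inherits(index, "feature_index"))
  if (nrow(blocks) == 0L) {
    return(tibble(gene_id = character(), label = character()))
  }
  if (!chrom %in% index$chroms) {
    if (is.null(index$warned[[chrom]])) {
      index$warned[[chrom]] <- TRUE
      warn(sprintf("chromosome '%s' absent from annotation; reads there get no feature",
                   chrom))
    }
    return(tibble(gene_id = character(), label = character()))
  }
  q <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(blocks$start + 1L, blocks$end))
  hits <- GenomicRanges::findOverlaps(q, index$gr, ignore.strand = TRUE)
  if (length(hits) == 0L) {
    return(tibble(gene_id = character(), label = character()))
  }
  sub <- index$gr[S4Vectors::subjectHits(hits)]
  tibble(gene_id = sub$gene_id, label = sub$label) |>
    group_by(.data$gene_id) |>
    summarise(label = if (any(.data$label == "exon")) "exon" else "intron",
              .groups = "drop")
}
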