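.COUNTERS <- c("umi_exon", "umi_intron", "internal_exon", "internal_intron",
               "dup_exon", "dup_intron")

#' Count one cell's BAM into per-gene UMI/internal/duplicate counters
#'
#' Composes [stream_assignments()] with per-gene, per-region
#' [dedup_gene()]. The exon/intron region of a pair is fixed at assignment
#' time, so a gene's exonic and intronic UMI pools are corrected and
#' deduplicated independently (a UMI observed in both pools counts once in
#' each). For every gene: `umi_*` is the deduplicated molecule count,
#' `dup_*` the raw UMI reads minus that, `internal_*` the internal pair
#' count.
#'
#' @param bam Path to the cell's BAM (or SAM).
#' @param index A [build_feature_index()] object.
#' @param cfg An [assignment_config()].
#' @param cell_id Cell identifier; defaults to the BAM basename.
#' @param count_offset Passed to [correct_umis()].
#' @return An object of class `"cell_counts"`: list with `cell_id`,
#'   `counts` (tibble `gene_id` + the six counters, one row per gene with
#'   any signal), `tally` (named category vector), `assignments` omitted
#'   for memory. Per gene and region,
#'   `umi_* + dup_*` equals that region's raw UMI read pairs.
#' @export
count_cell <- function(bam, index, cfg = assignment_config(),
                       cell_id = NULL, count_offset = 0L) {
  cell_id <- cell_id %||% sub("\\.(bam|sam)$", "", basename(bam))
  asn <- stream_assignments(bam, index, cfg)
  tally <- attr(asn, "tally")

  uniq <- asn |> filter(.data$category == "unique")
  counts <- tibble(gene_id = character(), counter = character(),
                   n = integer())
  if (nrow(uniq) > 0L) {
    counts <- uniq |>
      group_by(.data$gene_id, .data$region) |>
      summarise(res = list(dedup_gene(.data$umi, count_offset)),
                .groups = "drop") |>
      mutate(
        umi = purrr::map_int(.data$res, function(d)
          if (is.null(d$result)) 0L else d$result$n_unique),
        dup = purrr::map_int(.data$res, function(d)
          if (is.null(d$result)) 0L else d$result$n_duplicates),
        internal = purrr::map_int(.data$res, function(d)
          as.integer(d$n_internal))) |>
      select(-"res") |>
      tidyr::pivot_longer(c("umi", "dup", "internal"), names_to = "kind",
                          values_to = "n") |>
      mutate(counter = paste0(.data$kind, "_", .data$region)) |>
      select("gene_id", "counter", "n")
  }
  wide <- counts |>
    tidyr::pivot_wider(names_from = "counter", values_from = "n",
                       values_fill = 0L)
  for (cn in .COUNTERS) if (!cn %in% names(wide)) wide[[cn]] <- 0L
  wide <- wide |> select("gene_id", dplyr::all_of(.COUNTERS)) |>
    arrange(.data$gene_id)

  structure(list(cell_id = cell_id, counts = wide, tally = tally),
            class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf("cell_counts '%s': %d genes with signal\n",
              x$cell_id, nrow(x$counts)))
  print(x$tally)
  invisible(x)
}

#' @describeIn count_cell Tidy per-gene counter table of one cell.
#' @param x A `cell_counts` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.cell_counts <- function(x, ...) {
  x$counts |> mutate(cell_id = x$cell_id, .before = 1L)
}

#' @describeIn count_cell One-row cell summary: category tally, counter
#'   totals, and the duplicate fraction `dup / (dup + umi)`.
#' @exportS3Method generics::glance
glance.cell_counts <- function(x, ...) {
  tot <- colSums(x$counts[.COUNTERS])
  dup <- tot[["dup_exon"]] + tot[["dup_intron"]]
  umi <- tot[["umi_exon"]] + tot[["umi_intron"]]
  dplyr::bind_cols(
    tibble(cell_id = x$cell_id),
    as_tibble(as.list(x$tally)),
    as_tibble(as.list(tot)),
    tibble(duplicate_fraction = if (dup + umi > 0) dup / (dup + umi) else NA_real_))
}

#' Merge per-cell counts into six gene-by-cell matrices
#'
#' @param cells List of `cell_counts` objects (distinct `cell_id`s).
#' @param genes Ordered gene axis, normally `parse_gtf(...)$gene_id`; genes
#'   absent from a cell are zero. Column order is the input cell order,
#'   independent of any parallel completion order.
#' @return An object of class `"count_matrices"`: list with `genes`,
#'   `cells`, `matrices` (named list of six integer matrices: `umi_exon`,
#'   `umi_intron`, `internal_exon`, `internal_intron`, `dup_exon`,
#'   `dup_intron`), and `tallies` (per-cell category tallies).
#' @export
merge_cells <- function(cells, genes) {
  cell_ids <- vapply(cells, function(x) x$cell_id, character(1))
  if (anyDuplicated(cell_ids)) {
    abort(sprintf("duplicate cell_id '%s'", cell_ids[duplicated(cell_ids)][1L]))
  }
  mats <- lapply(.COUNTERS, function(cn) {
    m <- matrix(0L, nrow = length(genes), ncol = length(cells),
                dimnames = list(genes, cell_ids))
    for (j in seq_along(cells)) {
      cc <- cells[[j]]$counts
      keep <- cc$gene_id %in% genes
      m[cc$gene_id[keep], j] <- cc[[cn]][keep]
    }
    m
  })
  names(mats) <- .COUNTERS
  tallies <- lapply(cells, function(x) x$tally)
  names(tallies) <- cell_ids
  structure(list(genes = genes, cells = cell_ids, matrices = mats,
                 tallies = tallies),
            class = "count_matrices")
}

#' @export
print.count_matrices <- function(x, ...) {
  cat(sprintf("count_matrices: %d genes x %d cells (6 matrices)\n",
              length(x$genes), length(x$cells)))
  tot <- vapply(x$matrices, sum, numeric(1))
  print(tot)
  invisible(x)
}

#' @describeIn merge_cells Long tidy table: one row per
#'   (gene, cell, matrix) with a nonzero-inclusive `count`.
#' @param x A `count_matrices` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.count_matrices <- function(x, ...) {
  purrr::imap(x$matrices, function(m, nm) {
    as_tibble(as.data.frame.table(m, stringsAsFactors = FALSE)) |>
      setNames(c("gene_id", "cell_id", "count")) |>
      mutate(matrix = nm, count = as.integer(.data$count))
  }) |>
    bind_rows() |>
    select("matrix", "gene_id", "cell_id", "count")
}

#' @describeIn merge_cells Per-cell summary: library size (raw UMI reads),
#'   unique molecules, duplicate fraction.
#' @exportS3Method generics::glance
glance.count_matrices <- function(x, ...) {
  umi <- colSums(x$matrices$umi_exon) + colSums(x$matrices$umi_intron)
  dup <- colSums(x$matrices$dup_exon) + colSums(x$matrices$dup_intron)
  internal <- colSums(x$matrices$internal_exon) +
    colSums(x$matrices$internal_intron)
  tibble(cell_id = x$cells,
         umi_molecules = as.integer(umi),
         umi_duplicates = as.integer(dup),
         internal_reads = as.integer(internal),
         umi_library_size = as.integer(umi + dup),
         duplicate_fraction = ifelse(umi + dup > 0, dup / (umi + dup), NA_real_))
}

#' Quantify a cohort of cell BAMs into count matrices
#'
#' Top-level driver: parses the GTF once, counts every cell (optionally in
#' parallel — cells are independent work units and results are merged in
#' the declared input order, so outputs do not depend on worker scheduling),
#' merges into six matrices and optionally writes them.
#'
#' @param bams Character vector of per-cell BAM paths (plate-based
#'   convention: one BAM per cell, one column per BAM).
#' @param gtf GTF path, or a prebuilt [build_feature_index()] object.
#' @param cfg An [assignment_config()].
#' @param cell_ids Cell names; default BAM basenames.
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @param outdir If non-`NULL`, matrices and a run report are written there
#'   via [write_matrices()].
#' @param count_offset Passed to [correct_umis()].
#' @return A `count_matrices` object.
#' @export
count_cells <- function(bams, gtf, cfg = assignment_config(),
                        cell_ids = NULL, workers = 1L, outdir = NULL,
                        count_offset = 0L) {
  index <- if (inherits(gtf, "feature_index")) gtf else
    build_feature_index(parse_gtf(gtf))
  cell_ids <- cell_ids %||% sub("\\.(bam|sam)$", "", basename(bams))
  stopifnot(length(cell_ids) == length(bams))

  one <- function(j) {
    tryCatch(
      count_cell(bams[j], index, cfg, cell_id = cell_ids[j],
                 count_offset = count_offset),
      error = function(e) {
        warn(sprintf("cell '%s' failed and was skipped: %s",
                     cell_ids[j], conditionMessage(e)))
        NULL
      })
  }
  cells <- if (workers > 1L) {
    parallel::mclapply(seq_along(bams), one, mc.cores = workers)
  } else {
    lapply(seq_along(bams), one)
  }
  cells <- cells[!vapply(cells, is.null, logical(1))]
  m <- merge_cells(cells, index$genes)
  if (!is.null(outdir)) write_matrices(m, outdir)
  m
}
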