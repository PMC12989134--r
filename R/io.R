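#' Write count matrices to TSV, MatrixMarket and a run report
#'
#' Each of the six matrices is written twice: as a dense TSV (first column
#' `gene_id`, one column per cell) and as a MatrixMarket sparse triplet
#' (`<name>.mtx`), with shared `genes.tsv` / `cells.tsv` axis sidecars.
#' `report.json` carries the per-cell category tallies and any extraction
#' statistics passed in.
#'
#' @param m A `count_matrices` object from [merge_cells()].
#' @param outdir Output directory (created if needed).
#' @param extraction_stats Optional named list/tibble of per-cell
#'   [extract_umis()] statistics to embed in the report.
#' @return `outdir`, invisibly.
#' @export
write_matrices <- function(m, outdir, extraction_stats = NULL) {
  stopifnot(inherits(m, "count_matrices"))
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE,
                                         showWarnings = FALSE)
  if (!ok || file.access(outdir, 2L) != 0L) {
    abort(sprintf("cannot write to output directory '%s'", outdir))
  }
  for (nm in names(m$matrices)) {
    mat <- m$matrices[[nm]]
    tsv <- dplyr::bind_cols(tibble(gene_id = m$genes),
                            as_tibble(as.data.frame(mat)))
    readr::write_tsv(tsv, file.path(outdir, paste0(nm, ".tsv")))
    sm <- methods::as(Matrix::Matrix(mat, sparse = TRUE), "generalMatrix")
    Matrix::writeMM(sm, file.path(outdir, paste0(nm, ".mtx")))
  }
  writeLines(m$genes, file.path(outdir, "genes.tsv"))
  writeLines(m$cells, file.path(outdir, "cells.tsv"))
  report <- list(
    n_genes = length(m$genes),
    n_cells = length(m$cells),
    category_tally = m$tallies,
    extraction_stats = extraction_stats)
  jsonlite::write_json(report, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}

#' Read count matrices back from a [write_matrices()] directory
#'
#' @param outdir Directory written by [write_matrices()].
#' @return A `count_matrices` object (tallies restored from the report
#'   when present).
#' @export
read_matrices <- function(outdir) {
  genes <- readLines(file.path(outdir, "genes.tsv"))
  cells <- readLines(file.path(outdir, "cells.tsv"))
  mats <- lapply(.COUNTERS, function(nm) {
    tsv <- readr::read_tsv(file.path(outdir, paste0(nm, ".tsv")),
                           show_col_types = FALSE)
    mat <- as.matrix(tsv[, -1L, drop = FALSE])
    storage.mode(mat) <- "integer"
    rownames(mat) <- tsv$gene_id
    if (ncol(mat) > 0L) colnames(mat) <- cells
    mat
  })
  names(mats) <- .COUNTERS
  tallies <- NULL
  rp <- file.path(outdir, "report.json")
  if (file.exists(rp)) {
    rep <- jsonlite::read_json(rp)
    tallies <- lapply(rep$category_tally, function(x)
      setNames(as.integer(unlist(x)), names(x)))
  }
  structure(list(genes = genes, cells = cells, matrices = mats,
                 tallies = tallies),
            class = "count_matrices")
}

#' Saturation plot: duplicate fraction versus UMI library size
#'
#' One point per cell: x is the raw UMI read count (molecules +
#' duplicates), y the fraction of those reads that were PCR duplicates.
#' Computable from the output matrices alone; rising curves indicate
#' sequencing past the library's complexity.
#'
#' @param m A `count_matrices` object.
#' @return A ggplot object.
#' @export
plot_saturation <- function(m) {
  g <- glance(m)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$umi_library_size,
                                  y = .data$duplicate_fraction)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "UMI reads per cell (molecules + duplicates)",
                  y = "duplicate fraction",
                  title = "UMI saturation") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_saturation `autoplot` method; `type = "saturation"`
#'   (default) or `"totals"` (per-cell counter totals, stacked).
#' @param object A `count_matrices` object.
#' @param type Plot flavour.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.count_matrices <- function(object, type = c("saturation", "totals"),
                                    ...) {
  type <- match.arg(type)
  if (type == "saturation") return(plot_saturation(object))
  df <- tidy(object) |>
    group_by(.data$cell_id, .data$matrix) |>
    summarise(count = sum(.data$count), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cell_id, y = .data$count,
                                   fill = .data$matrix)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "read pairs", fill = NULL,
                  title = "Per-cell counter totals") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
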