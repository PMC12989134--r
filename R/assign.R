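#' Configuration for read-pair assignment
#'
#' @param count_primary_multimappers When `TRUE`, a multimapping pair is
#'   assigned using only its primary alignment (zUMIs-compatible mode);
#'   when `FALSE` (default) multimapping pairs land in the `multimapping`
#'   category.
#' @param stranded `"none"` (default), `"forward"` or `"reverse"`. With
#'   `"forward"` a gene is only eligible when its annotated strand equals
#'   the strand of the pair's first mate; `"reverse"` requires the
#'   opposite. Smart-seq3 5' reads are not reliably strand-informative, so
#'   unstranded is the default.
#' @param min_mapq Minimum MAPQ for a mate to participate; default 0
#'   (no filter).
#' @return A list of class `"assignment_config"`.
#' @export
assignment_config <- function(count_primary_multimappers = FALSE,
                              stranded = c("none", "forward", "reverse"),
                              min_mapq = 0L) {
  stranded <- match.arg(stranded)
  structure(
    list(count_primary_multimappers = isTRUE(count_primary_multimappers),
         stranded = stranded, min_mapq = as.integer(min_mapq)),
    class = "assignment_config")
}

.CATEGORIES <- c("unmapped", "no_feature", "multimapping", "ambiguous", "unique")

# flag-bit helpers
.bit <- function(flag, bit) bitwAnd(flag, bit) != 0L

# Pull the UMI payload off a read name tagged "<id>_<UMI>"; NA = internal.
.umi_from_name <- function(qname, umi_length = NULL) {
  m <- regmatches(qname, regexpr("_[ACGT]+$", qname))
  out <- rep(NA_character_, length(qname))
  hit <- grepl("_[ACGT]+$", qname)
  out[hit] <- sub("^_", "", regmatches(qname, regexpr("_[ACGT]+$", qname)))
  if (!is.null(umi_length)) out[!is.na(out) & nchar(out) != umi_length] <- NA
  out
}

# Read all alignment records of a BAM (or SAM, converted on the fly) into a
# flat tibble; one row per record.
.read_bam_records <- function(bam) {
  if (grepl("\\.sam$", bam)) {
    # htslib truncates silently on a bad CIGAR; validate before converting
    lns <- readLines(bam)
    body <- lns[!startsWith(lns, "@")]
    if (length(body)) {
      f <- strsplit(body, "\t", fixed = TRUE)
      cig <- vapply(f, `[[`, character(1), 6L)
      bad <- !grepl("^(\\*|([0-9]+[MIDNSHP=X])+)$", cig)
      if (any(bad)) {
        abort(sprintf("malformed CIGAR '%s' on read '%s'",
                      cig[bad][1L], vapply(f, `[[`, character(1), 1L)[bad][1L]))
      }
    }
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(bam, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar"),
    tag = "NH")
  res <- Rsamtools::scanBam(bam, param = p)[[1L]]
  nh <- res$tag$NH %||% rep(NA_integer_, length(res$qname))
  if (length(nh) == 0L) nh <- rep(NA_integer_, length(res$qname))
  tibble(
    qname = res$qname,
    flag = res$flag,
    rname = as.character(res$rname),
    pos = res$pos,
    mapq = res$mapq,
    cigar = res$cigar,
    nh = nh)
}

#' Classify every read pair of a BAM against a feature index
#'
#' Streams the alignments of one cell, groups records by read name, and
#' assigns each distinct pair to exactly one category by a first-match
#' cascade: `unmapped` (no usable aligned mate), `multimapping` (more than
#' one reported alignment, unless primary-alignment counting is enabled),
#' then by the union of both mates' aligned blocks over the index:
#' `no_feature` (no gene), `ambiguous` (more than one gene), or `unique`
#' (one gene, labelled exonic if any overlapped base of that gene is
#' exonic, else intronic). Secondary and supplementary records never vote.
#' The UMI payload is recovered from the `"_<UMI>"` read-name suffix
#' written by [extract_umis()]; names without it are internal reads.
#'
#' @param bam Path to a BAM (or SAM) file of one cell. Any sort order:
#'   records are bundled by name.
#' @param index A [build_feature_index()] object.
#' @param cfg An [assignment_config()].
#' @return A tibble with one row per distinct read name: `read_id`,
#'   `category`, `gene_id`, `region` (`"exon"`/`"intron"`; both `NA`
#'   unless `category == "unique"`), `umi` (`NA` for internal reads).
#'   The per-category tally is attached as `attr(, "tally")`, a named
#'   integer vector summing to the number of pairs.
#' @export
stream_assignments <- function(bam, index, cfg = assignment_config()) {
  rec <- .read_bam_records(bam)
  if (nrow(rec) == 0L) {
    out <- tibble(read_id = character(), category = character(),
                  gene_id = character(), region = character(),
                  umi = character())
    attr(out, "tally") <- setNames(integer(length(.CATEGORIES)), .CATEGORIES)
    return(out)
  }

  bad_cigar <- !is.na(rec$cigar) &
    !grepl("^(\\*|([0-9]+[MIDNSHP=X])+)$", rec$cigar)
  if (any(bad_cigar)) {
    abort(sprintf("malformed CIGAR '%s' on read '%s'",
                  rec$cigar[bad_cigar][1L], rec$qname[bad_cigar][1L]))
  }

  rec <- rec |>
    mutate(
      unmapped = .bit(.data$flag, 4L),
      secondary = .bit(.data$flag, 256L),
      supplementary = .bit(.data$flag, 2048L),
      reverse = .bit(.data$flag, 16L),
      mate1 = !.bit(.data$flag, 128L),   # first-of-pair or unpaired
      used = !.data$unmapped & !.data$secondary & !.data$supplementary &
        .data$mapq >= cfg$min_mapq)

  # per-pair multimapping evidence: NH tag, or several records for one mate
  pair_info <- rec |>
    group_by(.data$qname) |>
    summarise(
      multi = any(.data$nh > 1L, na.rm = TRUE) ||
        any(.data$secondary) ||
        sum(.data$mate1 & !.data$secondary & !.data$supplementary) > 1L ||
        sum(!.data$mate1 & !.data$secondary & !.data$supplementary) > 1L,
      n_used = sum(.data$used),
      strand1 = if (any(.data$used & .data$mate1))
        ifelse(.data$reverse[.data$used & .data$mate1][1L], "-", "+")
        else NA_character_,
      .groups = "drop")

  used <- rec |> filter(.data$used)

  # aligned reference blocks of every used record, vectorized
  feats <- NULL
  if (nrow(used) > 0L) {
    rng <- GenomicAlignments::extractAlignmentRangesOnReference(
      used$cigar, pos = used$pos, drop.D.ranges = FALSE)
    nblk <- S4Vectors::elementNROWS(rng)
    blk <- GenomicRanges::GRanges(rep(used$rname, nblk), unlist(rng))
    known <- as.character(GenomeInfoDb::seqnames(blk)) %in% index$chroms
    rec_of_blk <- rep(seq_len(nrow(used)), nblk)
    unknown_chroms <- unique(as.character(GenomeInfoDb::seqnames(blk))[!known])
    for (uc in unknown_chroms) {
      if (is.null(index$warned[[uc]])) {
        index$warned[[uc]] <- TRUE
        warn(sprintf(
          "chromosome '%s' absent from annotation; reads there get no feature", uc))
      }
    }
    if (any(known)) {
      hits <- GenomicRanges::findOverlaps(
        blk[known],
        GenomicRanges::GRanges(
          GenomeInfoDb::seqnames(index$gr),
          IRanges::ranges(index$gr)))
      if (length(hits) > 0L) {
        sub <- index$gr[S4Vectors::subjectHits(hits)]
        feats <- tibble(
          qname = used$qname[rec_of_blk[known][S4Vectors::queryHits(hits)]],
          gene_id = sub$gene_id,
          label = sub$label) |>
          distinct()
      }
    }
  }
  if (is.null(feats)) {
    feats <- tibble(qname = character(), gene_id = character(),
                    label = character())
  }

  if (cfg$stranded != "none") {
    gstr <- index$gene_strand
    feats <- feats |>
      left_join(pair_info |> select("qname", "strand1"), by = "qname") |>
      filter(!is.na(.data$strand1), gstr[.data$gene_id] != ".",
             if (cfg$stranded == "forward") gstr[.data$gene_id] == .data$strand1
             else gstr[.data$gene_id] != .data$strand1) |>
      select(-"strand1")
  }

  # exon dominance per (pair, gene), then gene count per pair
  gene_feats <- feats |>
    group_by(.data$qname, .data$gene_id) |>
    summarise(label = if (any(.data$label == "exon")) "exon" else "intron",
              .groups = "drop")
  per_pair_feats <- gene_feats |>
    group_by(.data$qname) |>
    summarise(n_genes = dplyr::n(),
              gene_id = .data$gene_id[1L],
              region = .data$label[1L],
              .groups = "drop")

  out <- pair_info |>
    left_join(per_pair_feats, by = "qname") |>
    mutate(
      n_genes = dplyr::coalesce(.data$n_genes, 0L),
      category = case_when(
        .data$n_used == 0L ~ "unmapped",
        .data$multi & !cfg$count_primary_multimappers ~ "multimapping",
        .data$n_genes == 0L ~ "no_feature",
        .data$n_genes >= 2L ~ "ambiguous",
        TRUE ~ "unique"),
      gene_id = ifelse(.data$category == "unique", .data$gene_id, NA_character_),
      region = ifelse(.data$category == "unique", .data$region, NA_character_),
      umi = .umi_from_name(.data$qname),
      read_id = .data$qname) |>
    select("read_id", "category", "gene_id", "region", "umi")

  tally <- table(factor(out$category, levels = .CATEGORIES))
  attr(out, "tally") <- setNames(as.integer(tally), .CATEGORIES)
  out
}

#' Classify one name-grouped alignment bundle
#'
#' Convenience wrapper over the same cascade as [stream_assignments()] for
#' a single pair given as a tibble of its alignment records (columns
#' `qname`, `flag`, `rname`, `pos`, `mapq`, `cigar`, `nh`). All records of
#' the bundle must share one read name.
#'
#' @param records Tibble of the pair's alignment records.
#' @param index A [build_feature_index()] object.
#' @param cfg An [assignment_config()].
#' @return A one-row assignment tibble (see [stream_assignments()]).
#' @export
classify_pair <- function(records, index, cfg = assignment_config()) {
  if (length(unique(records$qname)) != 1L) {
    abort("classify_pair() expects records of exactly one read name")
  }
  if (!"nh" %in% names(records)) records$nh <- NA_integer_
  tmp <- tempfile(fileext = ".sam")
  on.exit(unlink(tmp), add = TRUE)
  .write_sam(records, index, tmp)
  res <- stream_assignments(tmp, index, cfg)
  attr(res, "tally") <- NULL
  res
}

# minimal SAM writer for classify_pair round-tripping; header from index
.write_sam <- function(records, index, path) {
  spans <- tibble(chrom = as.character(GenomeInfoDb::seqnames(index$gr)),
                  end = GenomicRanges::end(index$gr)) |>
    group_by(.data$chrom) |>
    summarise(len = max(.data$end) + 10000L, .groups = "drop")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", spans$chrom, spans$len))
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    mapped <- bitwAnd(r$flag, 4L) == 0L
    paste(r$qname, r$flag,
          if (mapped) r$rname else "*",
          if (mapped) r$pos else 0L,
          if (is.na(r$mapq)) 255L else r$mapq,
          if (mapped && !is.na(r$cigar)) r$cigar else "*",
          "*", 0L, 0L, "*", "*",
          if (!is.na(r$nh)) sprintf("NH:i:%d", r$nh) else "",
          sep = "\t")
  }, character(1))
  body <- sub("\t$", "", body)
  writeLines(c(hdr, body), path)
  invisible(path)
}
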