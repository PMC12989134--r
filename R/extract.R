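#' Configuration for Smart-seq3 UMI extraction
#'
#' Describes the molecular construct expected at the start of read 1 of a
#' UMI-containing pair — anchor (template-switching oligo), UMI, trailing
#' trinucleotide — and the tolerances of the fuzzy matcher.
#'
#' @param anchor Anchor (TSO) sequence; default `"ATTGCGCAATG"` (11 nt).
#' @param trailing Trailing sequence after the UMI; default `"GGG"`.
#' @param umi_length UMI length in nt; default 8.
#' @param max_anchor_mismatches Maximum Hamming mismatches tolerated in the
#'   anchor window during fuzzy matching; default 1.
#' @param max_trailing_mismatches Maximum mismatches in the trailing window
#'   during fuzzy matching; default 1. Strict matching always requires an
#'   exact trailing match.
#' @param max_shift Maximum start offset (nt) of the anchor from read
#'   position 0 during fuzzy matching; default 2.
#' @param fuzzy_enabled Whether the fuzzy phase runs at all; default `TRUE`.
#'   With `FALSE` only exact, unshifted constructs are recognised
#'   (position-based detection).
#' @return A list of class `"extraction_config"`.
#' @examples
#' extraction_config()
#' extraction_config(fuzzy_enabled = FALSE)
#' @export
extraction_config <- function(anchor = "ATTGCGCAATG",
                              trailing = "GGG",
                              umi_length = 8L,
                              max_anchor_mismatches = 1L,
                              max_trailing_mismatches = 1L,
                              max_shift = 2L,
                              fuzzy_enabled = TRUE) {
  anchor <- toupper(anchor)
  trailing <- toupper(trailing)
  if (!grepl("^[ACGT]+$", anchor) || !grepl("^[ACGT]+$", trailing)) {
    abort("anchor and trailing must be non-empty and contain only A, C, G, T")
  }
  umi_length <- as.integer(umi_length)
  max_anchor_mismatches <- as.integer(max_anchor_mismatches)
  max_trailing_mismatches <- as.integer(max_trailing_mismatches)
  max_shift <- as.integer(max_shift)
  if (umi_length < 1L) abort("umi_length must be >= 1")
  if (max_anchor_mismatches < 0L || max_anchor_mismatches >= nchar(anchor)) {
    abort("max_anchor_mismatches must be in [0, length(anchor) - 1]")
  }
  if (max_trailing_mismatches < 0L || max_trailing_mismatches > nchar(trailing)) {
    abort("max_trailing_mismatches must be in [0, length(trailing)]")
  }
  if (max_shift < 0L) abort("max_shift must be >= 0")
  structure(
    list(anchor = anchor, trailing = trailing, umi_length = umi_length,
         max_anchor_mismatches = max_anchor_mismatches,
         max_trailing_mismatches = max_trailing_mismatches,
         max_shift = max_shift, fuzzy_enabled = isTRUE(fuzzy_enabled)),
    class = "extraction_config"
  )
}

#' @export
print.extraction_config <- function(x, ...) {
  cat("Smart-seq3 extraction config\n")
  cat(sprintf("  construct: %s + UMI(%d nt) + %s\n",
              x$anchor, x$umi_length, x$trailing))
  cat(sprintf("  fuzzy: %s (anchor mm <= %d, trailing mm <= %d, shift <= %d)\n",
              if (x$fuzzy_enabled) "on" else "off",
              x$max_anchor_mismatches, x$max_trailing_mismatches, x$max_shift))
  invisible(x)
}

# Vectorized anchor scan over a character vector of read-1 sequences.
# Returns a tibble with one row per read: start (0-based), mismatches,
# trailing_mismatches, mode ("strict"/"fuzzy"/NA for no hit).
.scan_anchor_vec <- function(seqs, cfg) {
  n <- length(seqs)
  alen <- nchar(cfg$anchor)
  tlen <- nchar(cfg$trailing)
  clen <- alen + cfg$umi_length + tlen
  len <- nchar(seqs)

  start <- rep(NA_integer_, n)
  amm <- rep(NA_integer_, n)
  tmm <- rep(NA_integer_, n)
  mode <- rep(NA_character_, n)

  eligible <- len >= clen
  if (any(eligible)) {
    a0 <- .pattern_mismatches(seqs, cfg$anchor, 1L)
    t0 <- .pattern_mismatches(seqs, cfg$trailing, alen + cfg$umi_length + 1L)
    strict <- eligible & a0 == 0L & t0 == 0L
    start[strict] <- 0L
    amm[strict] <- 0L
    tmm[strict] <- 0L
    mode[strict] <- "strict"

    if (cfg$fuzzy_enabled) {
      undecided <- eligible & !strict
      for (s in 0:cfg$max_shift) {
        if (!any(undecided)) break
        fits <- undecided & (len >= s + clen)
        if (!any(fits)) next
        am <- if (s == 0L) a0 else .pattern_mismatches(seqs, cfg$anchor, s + 1L)
        tm <- if (s == 0L) t0 else
          .pattern_mismatches(seqs, cfg$trailing, s + alen + cfg$umi_length + 1L)
        hit <- fits & am <= cfg$max_anchor_mismatches &
          tm <= cfg$max_trailing_mismatches
        if (any(hit)) {
          start[hit] <- s
          amm[hit] <- am[hit]
          tmm[hit] <- tm[hit]
          mode[hit] <- "fuzzy"
          undecided <- undecided & !hit
        }
      }
    }
  }
  tibble(start = start, mismatches = amm,
         trailing_mismatches = tmm, mode = mode)
}

#' Locate the anchor + UMI + trailing construct in a read sequence
#'
#' Two-phase search. Strict phase: the read must begin with the exact anchor
#' at offset 0 and carry the exact trailing sequence immediately after the
#' UMI window. Fuzzy phase (if enabled): start offsets `0..max_shift` are
#' scanned in increasing order and the first offset whose anchor and
#' trailing windows fall within the configured Hamming tolerances wins
#' (leftmost offset, then fewest total mismatches).
#'
#' @param read1_seq Character scalar, the read-1 sequence.
#' @param cfg An [extraction_config()].
#' @return A one-row tibble with columns `start` (0-based anchor offset),
#'   `mismatches`, `trailing_mismatches`, `mode` (`"strict"` or `"fuzzy"`),
#'   or `NULL` when no qualifying window exists (including reads shorter
#'   than the construct).
#' @examples
#' cfg <- extraction_config()
#' scan_anchor(paste0("ATTGCGCAATG", "ACGTACGT", "GGG", "TTTTTT"), cfg)
#' scan_anchor("TTTTTTTTTTTTTTTTTTTTTTTTTT", cfg)
#' @export
scan_anchor <- function(read1_seq, cfg = extraction_config()) {
  stopifnot(is.character(read1_seq), length(read1_seq) == 1L)
  hit <- .scan_anchor_vec(toupper(read1_seq), cfg)
  if (is.na(hit$start)) return(NULL)
  hit
}

# Core tagging step shared by extract_umi() and extract_umis(): classify a
# batch of read-1 sequences and compute UMI / trimmed payload per read.
.tag_reads <- function(seq1, qual1, cfg) {
  seq1 <- toupper(seq1)
  hits <- .scan_anchor_vec(seq1, cfg)
  alen <- nchar(cfg$anchor)
  tlen <- nchar(cfg$trailing)
  clen <- alen + cfg$umi_length + tlen

  umi_start <- hits$start + alen + 1L           # 1-based
  umi <- ifelse(is.na(hits$start), NA_character_,
                substr(seq1, umi_start, umi_start + cfg$umi_length - 1L))
  has_n <- !is.na(umi) & grepl("N", umi, fixed = TRUE)

  status <- dplyr::case_when(
    is.na(hits$start) ~ "internal_read",
    has_n ~ "rejected",
    TRUE ~ "umi_read"
  )
  trim_from <- hits$start + clen + 1L
  keep <- status == "umi_read"
  trimmed_seq1 <- ifelse(keep, substring(seq1, trim_from), seq1)
  trimmed_qual1 <- ifelse(keep, substring(qual1, trim_from), qual1)
  umi[status != "umi_read"] <- NA_character_

  tibble(status = status, umi = umi, mode = hits$mode,
         trimmed_seq1 = trimmed_seq1, trimmed_qual1 = trimmed_qual1)
}

#' Tag a single read pair with its UMI extraction outcome
#'
#' Applies [scan_anchor()] to read 1. On a hit whose UMI window is free of
#' `N`, the pair is a UMI read: the construct is trimmed from sequence and
#' quality, and the UMI is appended to the read identifier as
#' `"<id>_<UMI>"` so any aligner preserves it. A hit whose UMI window
#' contains `N` is rejected (an ambiguous UMI cannot be deduplicated). No
#' hit means an ordinary internal cDNA read, left untouched. Read 2 is
#' never scanned: Smart-seq3 places the construct on the 5' read only.
#'
#' @param read_id Read identifier (without the `@`).
#' @param seq1,qual1 Read-1 sequence and quality strings.
#' @param seq2,qual2 Read-2 sequence and quality strings (passed through).
#' @param cfg An [extraction_config()].
#' @return A one-row tibble: `read_id` (tagged when a UMI was found),
#'   `status` (`"umi_read"`, `"internal_read"` or `"rejected"`), `umi`,
#'   `mode`, `trimmed_seq1`, `trimmed_qual1`, `seq2`, `qual2`.
#' @examples
#' extract_umi("r1", paste0("ATTGCGCAATG", "AAAAAAAA", "GGG", "TTTT"),
#'             strrep("I", 26), "ACGT", "IIII")
#' @export
extract_umi <- function(read_id, seq1, qual1, seq2 = "", qual2 = "",
                        cfg = extraction_config()) {
  stopifnot(length(seq1) == 1L, nchar(seq1) > 0L)
  tag <- .tag_reads(seq1, qual1, cfg)
  id <- if (tag$status == "umi_read") paste0(read_id, "_", tag$umi) else read_id
  tibble(read_id = id, status = tag$status, umi = tag$umi, mode = tag$mode,
         trimmed_seq1 = tag$trimmed_seq1, trimmed_qual1 = tag$trimmed_qual1,
         seq2 = seq2, qual2 = qual2)
}

.first_token <- function(x) sub("[ \t].*$", "", x)

#' Extract UMIs from a paired FASTQ file into tagged, trimmed FASTQ
#'
#' Streams a synchronized FASTQ pair, tags every UMI-containing pair
#' (strict, then fuzzy anchor matching), trims the construct from read 1,
#' appends the UMI to both mates' identifiers, and writes the tagged pair
#' files to be fed to any RNA-seq aligner. Gzip input/output is handled
#' transparently by file extension.
#'
#' Rejected pairs (anchor found but `N` inside the UMI window) are written
#' untrimmed to `rejected1`/`rejected2` when given, otherwise to the main
#' outputs, so every input pair appears exactly once across the outputs.
#'
#' @param in1,in2 Input FASTQ paths (read 1 / read 2).
#' @param out1,out2 Output FASTQ paths.
#' @param cfg An [extraction_config()].
#' @param rejected1,rejected2 Optional FASTQ paths for rejected pairs.
#' @return A one-row tibble of extraction statistics: `n_pairs`,
#'   `n_umi_strict`, `n_umi_fuzzy`, `n_internal`, `n_rejected`. The four
#'   outcome counters always sum to `n_pairs`.
#' @export
extract_umis <- function(in1, in2, out1, out2, cfg = extraction_config(),
                         rejected1 = NULL, rejected2 = NULL) {
  fq1 <- ShortRead::readFastq(in1)
  fq2 <- ShortRead::readFastq(in2)
  if (length(fq1) != length(fq2)) {
    abort(sprintf(
      "desynchronized FASTQ pair: %d records in read 1 vs %d in read 2",
      length(fq1), length(fq2)))
  }
  ids1 <- .first_token(as.character(ShortRead::id(fq1)))
  ids2 <- .first_token(as.character(ShortRead::id(fq2)))
  # mates conventionally share ids up to a /1 /2 suffix
  core1 <- sub("/[12]$", "", ids1)
  core2 <- sub("/[12]$", "", ids2)
  bad <- which(core1 != core2)
  if (length(bad)) {
    abort(sprintf(
      "desynchronized FASTQ pair at record %d: read-1 id '%s' vs read-2 id '%s'",
      bad[1L], ids1[bad[1L]], ids2[bad[1L]]))
  }

  seq1 <- as.character(ShortRead::sread(fq1))
  qual1 <- as.character(Biostrings::quality(Biostrings::quality(fq1)))
  tags <- .tag_reads(seq1, qual1, cfg)

  stats <- tibble(
    n_pairs = length(fq1),
    n_umi_strict = sum(tags$status == "umi_read" & tags$mode == "strict",
                       na.rm = TRUE),
    n_umi_fuzzy = sum(tags$status == "umi_read" & tags$mode == "fuzzy",
                      na.rm = TRUE),
    n_internal = sum(tags$status == "internal_read"),
    n_rejected = sum(tags$status == "rejected")
  )

  is_umi <- tags$status == "umi_read"
  new_ids1 <- ifelse(is_umi, paste0(ids1, "_", tags$umi), ids1)
  new_ids2 <- ifelse(is_umi, paste0(ids2, "_", tags$umi), ids2)

  divert <- !is.null(rejected1) && !is.null(rejected2)
  main <- if (divert) tags$status != "rejected" else rep(TRUE, length(fq1))

  .write_fq <- function(path, ids, seqs, quals) {
    if (file.exists(path)) unlink(path)
    obj <- ShortRead::ShortReadQ(
      sread = Biostrings::DNAStringSet(seqs),
      quality = Biostrings::BStringSet(quals),
      id = Biostrings::BStringSet(ids))
    ShortRead::writeFastq(obj, path, mode = "w",
                          compress = grepl("\\.gz$", path))
  }

  seq2 <- as.character(ShortRead::sread(fq2))
  qual2 <- as.character(Biostrings::quality(Biostrings::quality(fq2)))
  .write_fq(out1, new_ids1[main], tags$trimmed_seq1[main],
            tags$trimmed_qual1[main])
  .write_fq(out2, new_ids2[main], seq2[main], qual2[main])
  if (divert) {
    rej <- tags$status == "rejected"
    .write_fq(rejected1, ids1[rej], seq1[rej], qual1[rej])
    .write_fq(rejected2, ids2[rej], seq2[rej], qual2[rej])
  }
  stats
}

#' Fraction of UMI reads gained by fuzzy matching
#'
#' The headline extraction statistic: of all UMI reads recovered, the share
#' only the fuzzy (error-tolerant) phase found,
#' `n_umi_fuzzy / (n_umi_strict + n_umi_fuzzy)`.
#'
#' @param stats A stats tibble from [extract_umis()].
#' @return A numeric scalar in `[0, 1]`; `NaN` when no UMI reads were found.
#' @export
fuzzy_gain <- function(stats) {
  with(stats, n_umi_fuzzy / (n_umi_strict + n_umi_fuzzy))
}
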