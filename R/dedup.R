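#' Directional one-Hamming UMI correction and deduplication
#'
#' Collapses sequencing-error UMIs within one gene's tally. UMIs are
#' processed in descending raw-count order (ties broken lexicographically).
#' A UMI `b` is merged into a not-yet-merged UMI `a` when
#' `hamming(a, b) == 1` and `count(a) >= 2 * count(b) - count_offset`,
#' choosing the highest-count eligible parent (lexicographic tie-break).
#' Merged UMIs are frozen — they can neither receive children nor be
#' re-examined — which prevents chain merging and over-correction.
#' Eligibility always uses raw counts, never counts inflated by earlier
#' merges. The deduplicated molecule count is the number of surviving UMIs;
#' everything else is the PCR-duplicate count.
#'
#' @param tally A tibble/data frame with columns `umi` and `count`
#'   (raw read counts, all UMIs the same length), or a named integer
#'   vector.
#' @param count_offset Relaxation of the frequency rule; default 0
#'   implements "at least twice as frequent" (`>= 2c`). Set to 1 for
#'   UMI-tools directional parity (`>= 2c - 1`). With a positive offset a
#'   UMI that has already received children is kept and never merged away,
#'   so no UMI is ever both parent and child.
#' @return An object of class `"umi_dedup"`: a list with `corrected`
#'   (tibble `umi`, `count` after merging), `merges` (tibble `child`,
#'   `parent`, `child_count`, `parent_count`), `raw` (input tally),
#'   `n_unique` and `n_duplicates`. Always
#'   `n_unique + n_duplicates == sum(raw counts)`.
#' @examples
#' correct_umis(tibble::tibble(umi = c("AAAA", "AAAT"), count = c(10, 1)))
#' @export
correct_umis <- function(tally, count_offset = 0L) {
  if (!is.data.frame(tally)) {
    tally <- tibble(umi = names(tally), count = as.integer(tally))
  }
  stopifnot(all(c("umi", "count") %in% names(tally)))
  if (nrow(tally) == 0L) abort("correct_umis() needs a non-empty tally")
  if (any(tally$count < 1L)) abort("UMI counts must be >= 1")
  umi <- as.character(tally$umi)
  if (anyDuplicated(umi)) abort("duplicate UMI in tally")
  if (length(unique(nchar(umi))) != 1L) {
    abort("mixed UMI lengths in one tally")
  }
  cnt <- as.integer(tally$count)
  count_offset <- as.integer(count_offset)

  ord <- order(-cnt, umi, method = "radix")
  umi <- umi[ord]
  cnt <- cnt[ord]
  n <- length(umi)

  # pairwise 1-Hamming adjacency on the (small) per-gene UMI set
  chars <- do.call(rbind, strsplit(umi, "", fixed = TRUE))
  merged_into <- rep(NA_integer_, n)   # index of parent, NA = kept
  is_parent <- rep(FALSE, n)
  extra <- rep(0L, n)                  # child mass absorbed per parent

  for (b in seq_len(n)) {
    if (!is.na(merged_into[b])) next
    if (is_parent[b]) next   # a parent stays; no UMI is both parent and child
    cand <- which(is.na(merged_into) & seq_len(n) != b &
                    cnt >= 2L * cnt[b] - count_offset)
    if (length(cand) == 0L) next
    d1 <- cand[rowSums(chars[cand, , drop = FALSE] !=
                         matrix(chars[b, ], nrow = length(cand),
                                ncol = ncol(chars), byrow = TRUE)) == 1L]
    if (length(d1) == 0L) next
    best <- d1[order(-cnt[d1], umi[d1], method = "radix")][1L]
    merged_into[b] <- best
    is_parent[best] <- TRUE
    extra[best] <- extra[best] + cnt[b]
  }

  kept <- is.na(merged_into)
  corrected <- tibble(umi = umi[kept], count = cnt[kept] + extra[kept]) |>
    arrange(.data$umi)
  merges <- tibble(
    child = umi[!kept],
    parent = umi[merged_into[!kept]],
    child_count = cnt[!kept],
    parent_count = cnt[merged_into[!kept]])

  structure(
    list(corrected = corrected, merges = merges,
         raw = tibble(umi = umi, count = cnt) |> arrange(.data$umi),
         n_unique = nrow(corrected),
         n_duplicates = sum(cnt) - nrow(corrected)),
    class = "umi_dedup")
}

#' @export
print.umi_dedup <- function(x, ...) {
  cat(sprintf(
    "umi_dedup: %d raw reads, %d molecules, %d duplicates, %d merge(s)\n",
    sum(x$raw$count), x$n_unique, x$n_duplicates, nrow(x$merges)))
  invisible(x)
}

#' @describeIn correct_umis Tidy the corrected tally (one row per surviving
#'   UMI, with its post-merge count).
#' @param x An `umi_dedup` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.umi_dedup <- function(x, ...) x$corrected

#' @describeIn correct_umis One-row summary: raw reads, unique molecules,
#'   duplicates, number of merges.
#' @exportS3Method generics::glance
glance.umi_dedup <- function(x, ...) {
  tibble(n_raw = sum(x$raw$count), n_unique = x$n_unique,
         n_duplicates = x$n_duplicates, n_merges = nrow(x$merges))
}

#' Deduplicate one gene's assigned read pairs
#'
#' Splits a gene's payloads into UMI reads (tallied and corrected with
#' [correct_umis()]) and internal reads (counted as-is, one per pair; no
#' deduplication is possible without a UMI).
#'
#' @param umis Character vector of UMI payloads for the gene's uniquely
#'   assigned pairs; `NA` entries are internal reads.
#' @param count_offset Passed to [correct_umis()].
#' @return A list: `tally` (raw UMI tibble), `result` (`umi_dedup` or
#'   `NULL` when the gene has no UMI reads), `n_internal`.
#' @export
dedup_gene <- function(umis, count_offset = 0L) {
  n_internal <- sum(is.na(umis))
  u <- umis[!is.na(umis)]
  if (length(u) == 0L) {
    return(list(tally = tibble(umi = character(), count = integer()),
                result = NULL, n_internal = n_internal))
  }
  tal <- tibble(umi = u) |>
    count(.data$umi, name = "count") |>
    arrange(.data$umi)
  list(tally = tal, result = correct_umis(tal, count_offset),
       n_internal = n_internal)
}
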