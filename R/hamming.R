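#' Hamming distance between two equal-length strings
#'
#' Counts positions at which the two strings differ. Used throughout the
#' package for fuzzy anchor matching and directional UMI correction.
#'
#' @param a,b Character scalars of equal length.
#' @return Non-negative integer count of mismatching positions.
#' @examples
#' hamming("GGG", "GGG")
#' hamming("ACGT", "ACGA")
#' @export
hamming <- function(a, b) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b)) {
    abort(sprintf("hamming() requires equal-length strings (got %d and %d)",
                  nchar(a), nchar(b)))
  }
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Vectorized mismatch count of a fixed pattern against windows of `seqs`
# starting at 1-based position `start`. Positions past the end of a sequence
# count as mismatches; callers guard with length preconditions.
.pattern_mismatches <- function(seqs, pattern, start) {
  pat <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  mm <- integer(length(seqs))
  for (i in seq_along(pat)) {
    mm <- mm + (substr(seqs, start + i - 1L, start + i - 1L) != pat[i])
  }
  mm
}
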