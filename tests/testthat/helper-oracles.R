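# Independent brute-force oracles. Deliberately naive, loop-based literal
# transcriptions of the rules, sharing no code with the implementation.

oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  s <- 0L
  for (i in seq_along(ca)) if (ca[i] != cb[i]) s <- s + 1L
  s
}

# enumerate every (offset, window) pair and apply the strict-then-fuzzy
# decision literally
brute_scan_anchor <- function(read, cfg) {
  alen <- nchar(cfg$anchor)
  tlen <- nchar(cfg$trailing)
  clen <- alen + cfg$umi_length + tlen
  L <- nchar(read)
  if (L >= clen) {
    a <- substr(read, 1, alen)
    tr <- substr(read, alen + cfg$umi_length + 1, alen + cfg$umi_length + tlen)
    if (a == cfg$anchor && tr == cfg$trailing) {
      return(list(start = 0L, mismatches = 0L, trailing_mismatches = 0L,
                  mode = "strict"))
    }
  }
  if (!cfg$fuzzy_enabled) return(NULL)
  for (s in 0:cfg$max_shift) {
    if (L < s + clen) next
    am <- oracle_hamming(substr(read, s + 1, s + alen), cfg$anchor)
    tm <- oracle_hamming(
      substr(read, s + alen + cfg$umi_length + 1, s + clen), cfg$trailing)
    if (am <= cfg$max_anchor_mismatches && tm <= cfg$max_trailing_mismatches) {
      return(list(start = s, mismatches = am, trailing_mismatches = tm,
                  mode = "fuzzy"))
    }
  }
  NULL
}

# same hit/absent decision as a comparable-shape record for easy vector
# comparison (NA row when absent)
brute_scan_row <- function(read, cfg) {
  h <- brute_scan_anchor(read, cfg)
  if (is.null(h)) {
    return(data.frame(start = NA_integer_, mismatches = NA_integer_,
                      trailing_mismatches = NA_integer_,
                      mode = NA_character_))
  }
  data.frame(start = h$start, mismatches = h$mismatches,
             trailing_mismatches = h$trailing_mismatches, mode = h$mode)
}

# literal transcription of the directional merge rule: descending raw
# count (lexicographic tie-break), merge into unmerged 1-Hamming neighbour
# with raw count >= 2*child - offset, highest-count parent wins, merged
# UMIs frozen, parents never merged away
oracle_correct_umis <- function(umis, counts, offset = 0L) {
  o <- order(-counts, umis, method = "radix")
  umis <- umis[o]
  counts <- counts[o]
  n <- length(umis)
  alive <- rep(TRUE, n)
  was_parent <- rep(FALSE, n)
  corrected <- counts
  merges <- list()
  for (b in seq_len(n)) {
    if (!alive[b] || was_parent[b]) next
    cand <- integer(0)
    for (a in seq_len(n)) {
      if (a == b || !alive[a]) next
      if (oracle_hamming(umis[a], umis[b]) != 1L) next
      if (counts[a] >= 2L * counts[b] - offset) cand <- c(cand, a)
    }
    if (length(cand) == 0L) next
    best <- cand[order(-counts[cand], umis[cand], method = "radix")][1L]
    corrected[best] <- corrected[best] + counts[b]
    alive[b] <- FALSE
    was_parent[best] <- TRUE
    merges[[length(merges) + 1L]] <- c(child = umis[b], parent = umis[best])
  }
  res <- sort(setNames(corrected[alive], umis[alive]))
  list(corrected = res[order(names(res), method = "radix")],
       n_unique = sum(alive),
       n_duplicates = sum(counts) - sum(alive),
       merges = merges)
}

expect_dedup_matches_oracle <- function(umis, counts, offset = 0L) {
  got <- correct_umis(tibble::tibble(umi = umis, count = counts), offset)
  want <- oracle_correct_umis(umis, counts, offset)
  expect_identical(setNames(as.integer(got$corrected$count),
                            got$corrected$umi),
                   setNames(as.integer(want$corrected),
                            names(want$corrected)))
  expect_identical(got$n_unique, as.integer(want$n_unique))
  expect_identical(got$n_duplicates, as.integer(want$n_duplicates))
}

# naive per-position read-pair classifier over raw gene models; walks the
# CIGAR by hand and tests every covered base against every gene
naive_covered_positions <- function(pos, cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  covered <- integer(0)
  cur <- pos   # 1-based reference position
  for (op in ops) {
    len <- as.integer(sub("[MIDNSHP=X]", "", op))
    type <- sub("[0-9]+", "", op)
    if (type %in% c("M", "=", "X", "D")) {
      if (type != "D") covered <- c(covered, seq(cur, cur + len - 1L))
      else covered <- c(covered, seq(cur, cur + len - 1L))
      cur <- cur + len
    } else if (type == "N") {
      cur <- cur + len
    }
    # I, S, H, P consume no reference
  }
  covered
}

naive_classify_pair <- function(records, models, cpm = FALSE, min_mapq = 0L) {
  prim <- records[bitwAnd(records$flag, 256L) == 0L &
                    bitwAnd(records$flag, 2048L) == 0L, , drop = FALSE]
  used <- prim[bitwAnd(prim$flag, 4L) == 0L & prim$mapq >= min_mapq, ,
               drop = FALSE]
  if (nrow(used) == 0L) return(list(category = "unmapped"))
  n_m1 <- sum(bitwAnd(prim$flag, 128L) == 0L)
  n_m2 <- sum(bitwAnd(prim$flag, 128L) != 0L)
  multi <- any(records$nh > 1L, na.rm = TRUE) ||
    any(bitwAnd(records$flag, 256L) != 0L) || n_m1 > 1L || n_m2 > 1L
  if (multi && !cpm) return(list(category = "multimapping"))
  hits <- list()
  for (i in seq_len(nrow(used))) {
    covered <- naive_covered_positions(used$pos[i], used$cigar[i])
    for (g in seq_len(nrow(models))) {
      if (models$chrom[g] != used$rname[i]) next
      ex <- models$exons[[g]]
      for (p in covered) {
        p0 <- p - 1L    # 0-based
        if (p0 >= models$start[g] && p0 < models$end[g]) {
          in_ex <- any(p0 >= ex$start & p0 < ex$end)
          key <- models$gene_id[g]
          lab <- if (in_ex) "exon" else "intron"
          prev <- hits[[key]]
          hits[[key]] <- if (is.null(prev) || prev == "intron") lab else prev
        }
      }
    }
  }
  if (length(hits) == 0L) return(list(category = "no_feature"))
  if (length(hits) >= 2L) return(list(category = "ambiguous"))
  list(category = "unique", gene_id = names(hits)[1L],
       region = hits[[1L]])
}
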