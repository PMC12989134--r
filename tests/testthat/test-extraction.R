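test_that("hamming counts substitutions and rejects unequal lengths", {
  expect_identical(hamming("GGG", "GGG"), 0L)
  expect_identical(hamming("ATTGCGCAATG", "ATTGCGCAATG"), 0L)
  expect_identical(hamming("ACGT", "ACGA"), 1L)
  expect_error(hamming("AC", "ACG"), "equal-length")
  set.seed(11)
  for (i in 1:50) {
    a <- rand_seq(12)
    b <- rand_seq(12)
    expect_identical(hamming(a, b), hamming(b, a))
    expect_identical(hamming(a, b), oracle_hamming(a, b))
    expect_identical(hamming(a, a), 0L)
  }
})

test_that("scan_anchor finds strict, mutated and shifted constructs", {
  cfg <- extraction_config()
  cdna <- strrep("T", 30)

  hit <- scan_anchor(paste0("ATTGCGCAATG", "ACGTACGT", "GGG", cdna), cfg)
  expect_identical(hit$start, 0L)
  expect_identical(hit$mismatches, 0L)
  expect_identical(hit$mode, "strict")

  # one anchor substitution: fuzzy rescue, lost when fuzzy is off
  mut <- paste0("ATTGCGCAAAG", "ACGTACGT", "GGG", cdna)
  hit <- scan_anchor(mut, cfg)
  expect_identical(hit$start, 0L)
  expect_identical(hit$mismatches, 1L)
  expect_identical(hit$mode, "fuzzy")
  expect_null(scan_anchor(mut, extraction_config(fuzzy_enabled = FALSE)))

  # 1 nt shift
  hit <- scan_anchor(paste0("T", "ATTGCGCAATG", "ACGTACGT", "GGG", cdna), cfg)
  expect_identical(hit$start, 1L)
  expect_identical(hit$mode, "fuzzy")

  # too short for the construct
  expect_null(scan_anchor("ATTGCGCAATG", cfg))
})

test_that("scan_anchor agrees with the brute-force enumerator on random reads", {
  cfg <- extraction_config()
  set.seed(31)
  # bias the alphabet so near-anchor prefixes actually occur
  reads <- vapply(1:2000, function(i) {
    if (i %% 2 == 0) {
      u <- rand_seq(8)
      body <- paste0(rand_seq(sample(0:2, 1)), "ATTGCGCAATG", u,
                     rand_seq(3, c("G", "A")), rand_seq(20))
      # sprinkle substitutions
      n_mut <- sample(0:3, 1)
      for (k in seq_len(n_mut)) {
        p <- sample(nchar(body), 1)
        substr(body, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      body
    } else {
      rand_seq(sample(10:45, 1))
    }
  }, character(1))
  got <- umiquant:::.scan_anchor_vec(reads, cfg)
  want <- do.call(rbind, lapply(reads, brute_scan_row, cfg = cfg))
  expect_identical(got$start, want$start)
  expect_identical(got$mismatches, want$mismatches)
  expect_identical(got$trailing_mismatches, want$trailing_mismatches)
  expect_identical(got$mode, want$mode)
  # the exported scalar wrapper matches the vectorized path
  for (i in sample(length(reads), 25)) {
    h <- scan_anchor(reads[i], cfg)
    if (is.na(got$start[i])) expect_null(h)
    else expect_identical(h$start, got$start[i])
  }
})

test_that("extract_umi tags, trims, and rejects N-containing UMIs", {
  cdna <- strrep("T", 20)
  r <- extract_umi("r1", paste0("ATTGCGCAATG", "AAAAAAAA", "GGG", cdna),
                   strrep("I", 42))
  expect_identical(r$status, "umi_read")
  expect_identical(r$umi, "AAAAAAAA")
  expect_identical(r$trimmed_seq1, cdna)
  expect_identical(r$trimmed_qual1, strrep("I", 20))
  expect_identical(r$read_id, "r1_AAAAAAAA")

  r <- extract_umi("r2", strrep("T", 42), strrep("I", 42))
  expect_identical(r$status, "internal_read")
  expect_identical(r$trimmed_seq1, strrep("T", 42))
  expect_identical(r$read_id, "r2")

  r <- extract_umi("r3", paste0("ATTGCGCAATG", "AAANAAAA", "GGG", cdna),
                   strrep("I", 42))
  expect_identical(r$status, "rejected")
  expect_true(is.na(r$umi))
})

test_that("construct round-trips: zero-error reads return exactly UMI and payload", {
  cfg <- extraction_config()
  set.seed(5)
  for (i in 1:50) {
    u <- rand_seq(8)
    payload <- rand_seq(sample(20:60, 1))
    r <- extract_umi("x", DEFAULT_CONSTRUCT(u, payload),
                     strrep("I", 22 + nchar(payload)), cfg = cfg)
    expect_identical(r$umi, u)
    expect_identical(r$trimmed_seq1, payload)
  }
})

test_that("extract_umis reports the forced stats split on constructed inputs", {
  set.seed(91)
  umis <- vapply(1:60, function(i) rand_seq(8), character(1))
  seq_umi <- vapply(umis, function(u) DEFAULT_CONSTRUCT(u, rand_seq(40)),
                    character(1))
  # internal reads: plain A/T cDNA cannot resemble the G/C-bearing anchor
  seq_int <- vapply(1:40, function(i) rand_seq(62, c("A", "T")), character(1))
  ids <- sprintf("p%03d", 1:100)
  seq2 <- vapply(1:100, function(i) rand_seq(62), character(1))
  fq <- write_fastq_pair(ids, c(seq_umi, seq_int), seq2)

  out1 <- tempfile(fileext = ".fastq")
  out2 <- tempfile(fileext = ".fastq")
  st <- extract_umis(fq[1], fq[2], out1, out2)
  expect_identical(st$n_pairs, 100L)
  expect_identical(st$n_umi_strict, 60L)
  expect_identical(st$n_umi_fuzzy, 0L)
  expect_identical(st$n_internal, 40L)
  expect_identical(st$n_rejected, 0L)

  # mutate one anchor base in 10 of the 60 constructs
  seq_mut <- seq_umi
  for (i in 1:10) substr(seq_mut[i], 3, 3) <- "A"   # T -> A
  fq2 <- write_fastq_pair(ids, c(seq_mut, seq_int), seq2)
  st2 <- extract_umis(fq2[1], fq2[2], out1, out2)
  expect_identical(st2$n_umi_strict, 50L)
  expect_identical(st2$n_umi_fuzzy, 10L)
  expect_identical(st2$n_internal, 40L)

  # with fuzzy off the mutated constructs fall back to internal
  st3 <- extract_umis(fq2[1], fq2[2], out1, out2,
                      extraction_config(fuzzy_enabled = FALSE))
  expect_identical(st3$n_umi_strict, 50L)
  expect_identical(st3$n_umi_fuzzy, 0L)
  expect_identical(st3$n_internal, 50L)

  # partition invariant + fuzzy monotonicity
  for (s in list(st, st2, st3)) {
    expect_identical(s$n_pairs,
                     s$n_umi_strict + s$n_umi_fuzzy + s$n_internal +
                       s$n_rejected)
  }
  expect_gte(st2$n_umi_strict + st2$n_umi_fuzzy,
             st3$n_umi_strict + st3$n_umi_fuzzy)
  expect_identical(st2$n_umi_strict, st3$n_umi_strict)
})

test_that("extract_umis writes tagged, trimmed, order-preserving outputs", {
  u <- c("ACGTACGT", "TTTTCCCC")
  payload <- c(strrep("T", 30), strrep("A", 30))
  ids <- c("a1", "a2", "a3")
  seq1 <- c(DEFAULT_CONSTRUCT(u[1], payload[1]), strrep("A", 40),
            DEFAULT_CONSTRUCT(u[2], payload[2]))
  seq2 <- rep(strrep("C", 40), 3)
  fq <- write_fastq_pair(ids, seq1, seq2)
  out1 <- tempfile(fileext = ".fastq")
  out2 <- tempfile(fileext = ".fastq")
  extract_umis(fq[1], fq[2], out1, out2)

  r1 <- ShortRead::readFastq(out1)
  r2 <- ShortRead::readFastq(out2)
  expect_identical(as.character(ShortRead::id(r1)),
                   c("a1_ACGTACGT", "a2", "a3_TTTTCCCC"))
  expect_identical(as.character(ShortRead::id(r2)),
                   c("a1_ACGTACGT", "a2", "a3_TTTTCCCC"))
  expect_identical(as.character(ShortRead::sread(r1)),
                   c(payload[1], strrep("A", 40), payload[2]))
  # read 2 untouched
  expect_identical(as.character(ShortRead::sread(r2)), seq2)

  # determinism: identical inputs give byte-identical outputs
  o1b <- tempfile(fileext = ".fastq")
  o2b <- tempfile(fileext = ".fastq")
  extract_umis(fq[1], fq[2], o1b, o2b)
  expect_identical(readLines(o1b), readLines(out1))
})

test_that("rejected pairs are diverted when asked, kept in outputs otherwise", {
  seqN <- DEFAULT_CONSTRUCT("AAANAAAA", strrep("T", 30))
  seq1 <- c(seqN, DEFAULT_CONSTRUCT("CCCCCCCC", strrep("T", 30)))
  fq <- write_fastq_pair(c("n1", "k1"), seq1, rep(strrep("G", 30), 2))
  out1 <- tempfile(fileext = ".fastq"); out2 <- tempfile(fileext = ".fastq")
  rej1 <- tempfile(fileext = ".fastq"); rej2 <- tempfile(fileext = ".fastq")

  st <- extract_umis(fq[1], fq[2], out1, out2,
                     rejected1 = rej1, rejected2 = rej2)
  expect_identical(st$n_rejected, 1L)
  expect_identical(length(ShortRead::readFastq(out1)), 1L)
  rj <- ShortRead::readFastq(rej1)
  expect_identical(as.character(ShortRead::id(rj)), "n1")
  expect_identical(as.character(ShortRead::sread(rj)), seqN)  # untrimmed

  # without diversion every pair stays in the main outputs
  st <- extract_umis(fq[1], fq[2], out1, out2)
  expect_identical(length(ShortRead::readFastq(out1)), 2L)
})

test_that("empty and desynchronized FASTQ inputs are handled", {
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  writeLines(character(0), f1); writeLines(character(0), f2)
  st <- extract_umis(f1, f2, tempfile(fileext = ".fastq"),
                     tempfile(fileext = ".fastq"))
  expect_identical(st$n_pairs, 0L)
  expect_true(all(st[1, -1] == 0))

  fq <- write_fastq_pair(c("a", "b"), rep(strrep("A", 30), 2),
                         rep(strrep("C", 30), 2))
  f3 <- tempfile(fileext = ".fastq")
  writeLines(as.vector(rbind(paste0("@", c("a", "zzz")), strrep("C", 30), "+",
                             strrep("I", 30))), f3)
  expect_error(
    extract_umis(fq[1], f3, tempfile(), tempfile()),
    "record 2")
})

test_that("gzip FASTQ round-trips transparently", {
  u <- "ACACACAC"
  fqp <- write_fastq_pair("g1", DEFAULT_CONSTRUCT(u, strrep("T", 25)),
                          strrep("G", 25))
  gz1 <- paste0(tempfile(), ".fastq.gz")
  gz2 <- paste0(tempfile(), ".fastq.gz")
  # compress inputs
  writeLines(readLines(fqp[1]), gzfile(gz1)); writeLines(readLines(fqp[2]), gzfile(gz2))
  o1 <- paste0(tempfile(), ".fastq.gz"); o2 <- paste0(tempfile(), ".fastq.gz")
  st <- extract_umis(gz1, gz2, o1, o2)
  expect_identical(st$n_umi_strict, 1L)
  r1 <- ShortRead::readFastq(o1)
  expect_identical(as.character(ShortRead::id(r1)), paste0("g1_", u))
})
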