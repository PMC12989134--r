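# GA exon1 is chrT 1..200 (1-based), intron 201..800, exon2 801..1000;
# GB occupies 2001..2600; 1001..2000 and >2600 are intergenic.

test_that("a constructed 10-pair fixture lands in the expected categories", {
  sam <- toy_sam(c(
    sam_unmapped_pair("u1"),
    sam_unmapped_pair("u2"),
    c(sam_pair("m1", 50, 120, nh = 2),
      sam_rec("m1", 355L, 1200, nh = 2), sam_rec("m1", 403L, 1270, nh = 2)),
    sam_pair("i1", 1200, 1300),              # intergenic
    c(sam_rec("b1", 99L, 50), sam_rec("b1", 147L, 2050)),  # GA + GB
    sam_pair("q1_ACGTACGT", 50, 120),        # GA exon, UMI payload
    sam_pair("q2", 300, 400),                # GA intron, internal
    sam_pair("q3_TTTTAAAA", 850, 920),       # GA exon2
    sam_pair("q4", 2050, 2120),              # GB exon
    sam_pair("q5", 120, 220)                 # GA exon-boundary: exon dominates
  ))
  asn <- stream_assignments(sam, toy_index())
  tally <- attr(asn, "tally")
  expect_identical(tally, c(unmapped = 2L, no_feature = 1L,
                            multimapping = 1L, ambiguous = 1L, unique = 5L))
  expect_identical(sum(tally), nrow(asn))

  a <- asn[match(c("q1_ACGTACGT", "q2", "q3_TTTTAAAA", "q4", "q5"),
                 asn$read_id), ]
  expect_identical(a$gene_id, c("GA", "GA", "GA", "GB", "GA"))
  expect_identical(a$region, c("exon", "intron", "exon", "exon", "exon"))
  expect_identical(a$umi, c("ACGTACGT", NA, "TTTTAAAA", NA, NA))
})

test_that("empty BAM yields an empty assignment table and zero tally", {
  sam <- toy_sam(character(0))
  asn <- stream_assignments(sam, toy_index())
  expect_identical(nrow(asn), 0L)
  expect_true(all(attr(asn, "tally") == 0L))
})

test_that("primary-multimapper counting rescues only multimapping pairs", {
  sam <- toy_sam(c(
    c(sam_pair("m1", 50, 120, nh = 2),
      sam_rec("m1", 355L, 1200, nh = 2), sam_rec("m1", 403L, 1270, nh = 2)),
    sam_pair("s1", 850, 920),
    sam_pair("i1", 1200, 1300)))
  idx <- toy_index()

  off <- stream_assignments(sam, idx, assignment_config())
  expect_identical(off$category[off$read_id == "m1"], "multimapping")

  on <- stream_assignments(sam, idx,
                           assignment_config(count_primary_multimappers = TRUE))
  expect_identical(on$category[on$read_id == "m1"], "unique")
  expect_identical(on$gene_id[on$read_id == "m1"], "GA")
  expect_identical(on$region[on$read_id == "m1"], "exon")

  # all other pairs untouched; partition preserved
  for (id in c("s1", "i1")) {
    expect_identical(on$category[on$read_id == id],
                     off$category[off$read_id == id])
  }
  expect_identical(sum(attr(on, "tally")), sum(attr(off, "tally")))
})

test_that("pair-level rules: joint mate voting, singletons, MAPQ filter", {
  idx <- toy_index()
  # mate1 in GA intron, mate2 also intronic: unique intron
  sam <- toy_sam(sam_pair("p1", 300, 400))
  asn <- stream_assignments(sam, idx)
  expect_identical(asn$category, "unique")
  expect_identical(asn$region, "intron")

  # mate1 intron + mate2 exon of the same gene: exon dominates at pair level
  sam <- toy_sam(sam_pair("p2", 700, 801))
  asn <- stream_assignments(sam, idx)
  expect_identical(asn$region, "exon")

  # singleton mate (other unmapped) still assignable
  sam <- toy_sam(c(
    sam_rec("p3", 73L, 100),   # paired, mate unmapped, first of pair
    paste("p3", 133, "*", 0, 0, "*", "*", 0, 0, "*", "*", sep = "\t")))
  asn <- stream_assignments(sam, idx)
  expect_identical(asn$category, "unique")

  # MAPQ below threshold: pair treated as unmapped
  sam <- toy_sam(c(sam_rec("p4", 99L, 50, mapq = 3L),
                   sam_rec("p4", 147L, 120, mapq = 3L)))
  asn <- stream_assignments(sam, idx, assignment_config(min_mapq = 10L))
  expect_identical(asn$category, "unmapped")
})

test_that("mate order within a pair does not change assignments", {
  recs <- c(sam_rec("x1", 99L, 50), sam_rec("x1", 147L, 2050),
            sam_pair("x2", 300, 400))
  a1 <- stream_assignments(toy_sam(recs), toy_index())
  a2 <- stream_assignments(toy_sam(rev(recs)), toy_index())
  a1 <- a1[order(a1$read_id), ]
  a2 <- a2[order(a2$read_id), ]
  expect_identical(a1$category, a2$category)
  expect_identical(a1$gene_id, a2$gene_id)
})

test_that("malformed CIGAR strings are reported with the read name", {
  sam <- toy_sam(sam_pair("bad1", 50, 120, cigar = "50Q"))
  expect_error(stream_assignments(sam, toy_index()), "bad1")
})

test_that("UMI payloads come only from a valid read-name suffix", {
  sam <- toy_sam(c(sam_pair("r_ACGTACGT", 50, 120),
                   sam_pair("r_12", 300, 400),
                   sam_pair("plain", 850, 920)))
  asn <- stream_assignments(sam, toy_index())
  expect_identical(asn$umi[asn$read_id == "r_ACGTACGT"], "ACGTACGT")
  expect_true(is.na(asn$umi[asn$read_id == "r_12"]))
  expect_true(is.na(asn$umi[asn$read_id == "plain"]))
})

test_that("classifications match a naive per-position oracle on simulated cells", {
  fix <- categories_cohort()
  cell <- fix$coh$cells[[1]]
  models <- fix$coh$ref$models
  idx <- build_feature_index(models)
  for (cpm in c(FALSE, TRUE)) {
    asn <- stream_assignments(
      cell$bam, idx, assignment_config(count_primary_multimappers = cpm))
    rec <- umiquant:::.read_bam_records(cell$bam)
    # spot-check a category-stratified sample against the oracle
    set.seed(7)
    ids <- unlist(lapply(split(asn$read_id, asn$category), function(x)
      sample(x, min(50, length(x)))))
    for (id in ids) {
      want <- naive_classify_pair(rec[rec$qname == id, , drop = FALSE],
                                  models, cpm = cpm)
      got <- asn[asn$read_id == id, ]
      expect_identical(got$category, want$category)
      if (want$category == "unique") {
        expect_identical(got$gene_id, want$gene_id)
        expect_identical(got$region, want$region)
      }
    }
    expect_identical(sum(attr(asn, "tally")),
                     length(unique(rec$qname)))
  }
})
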