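rss_flank <- function(hept = "CACAGTG", non = "ACAAAAACC", spacer = 23) {
  paste0("ACGT", hept, strrep("A", spacer), non, "ACGT")
}

test_that("recombination signals are found with mismatch scoring", {
  hit <- find_rss(rss_flank(), 23)
  expect_equal(hit$score, 0)
  expect_equal(hit$heptamer, "CACAGTG")
  expect_equal(hit$spacer_length, 23)
  hit1 <- find_rss(rss_flank(non = "ACAAAAACG"), 23)
  expect_equal(hit1$score, 1)
  # broken CAC seed: no hit at all
  expect_null(find_rss(rss_flank(hept = "CTCAGTG"), 23))
  # a C/G-free flank cannot contain a CAC seed
  expect_null(find_rss(strrep("AT", 25), 23))
})

test_that("RSS scanning validates its input", {
  expect_error(find_rss("ACGT", 23), "shorter")
  expect_error(find_rss(strrep("A", 50), 15), "12 or 23")
})

test_that("V-REGION gapping places CDR loops with middle-out gaps", {
  set.seed(9)
  g <- gap_v_region(make_vaa(12, 10))
  expect_equal(g$cdr1_length, 12)
  expect_equal(g$cdr2_length, 10)
  expect_false(grepl("\\.", g$gapped_aa))
  expect_true(all(g$anchor_present))
  expect_equal(substr(g$gapped_aa, 23, 23), "C")
  expect_equal(substr(g$gapped_aa, 41, 41), "W")
  expect_equal(substr(g$gapped_aa, 104, 104), "C")

  g8 <- gap_v_region(make_vaa(8, 10))
  cdr1 <- substr(g8$gapped_aa, 27, 38)
  expect_equal(nchar(gsub("[^.]", "", cdr1)), 4)  # 12 - 8 gaps
  # gaps sit in the middle of the loop: flanks contiguous
  expect_match(cdr1, "^[^.]{4}\\.{4}[^.]{4}$")
  expect_equal(g8$cdr1_length, 8)
})

test_that("gapping fails without cysteine anchors", {
  set.seed(10)
  aa <- gsub("C", "A", make_vaa(10, 8))
  expect_error(gap_v_region(aa), "CYS")
})

test_that("functionality calls follow the F/ORF/P decision rules", {
  set.seed(11)
  v <- salmigh:::.build_v_ancestor(300)
  expect_equal(classify_functionality(v, flank_3p = rss_flank())$value, "F")

  # in-frame stop: pseudogene, frame open
  v_stop <- paste0(substr(v, 1, 87), "TAA", substring(v, 91))
  f <- classify_functionality(v_stop)
  expect_equal(f$value, "P")
  expect_true(f$in_frame)
  expect_true("STOP_CODON" %in% f$reasons)

  # single-base deletion: frameshifted pseudogene
  v_del <- paste0(substr(v, 1, 33), substring(v, 35))
  f <- classify_functionality(v_del)
  expect_equal(f$value, "P")
  expect_false(f$in_frame)
  expect_true("FRAMESHIFT" %in% f$reasons)

  # broken heptamer on an open frame: ORF with RSS defect
  f <- classify_functionality(v, flank_3p = rss_flank(hept = "CTCAGTG"))
  expect_equal(f$value, "ORF")
  expect_equal(f$reasons, "RSS_DEFECT")

  # strict mode reclassifies flank-only defects as in-frame P
  f <- classify_functionality(v, flank_3p = rss_flank(hept = "CTCAGTG"),
                              strict = TRUE)
  expect_equal(f$value, "P")
  expect_true(f$in_frame)

  # defective initiation context
  f <- classify_functionality(v, leader_nt = "CTGGCAGCA")
  expect_equal(f$value, "P")
  expect_true("NO_INIT" %in% f$reasons)

  # anchor loss on an open frame: ORF
  v_anch <- v
  substr(v_anch, 67, 69) <- "GCA"  # codon 23 no longer cysteine
  f <- classify_functionality(v_anch)
  expect_equal(f$value, "ORF")
  expect_true("CONSERVED_AA_CHANGE" %in% f$reasons)

  expect_error(classify_functionality(NULL), "required")
})
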