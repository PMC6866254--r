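salmon_tbl <- read_gene_table(fixture("salmon_ighv_genetable_synthetic.tsv"))
trout_tbl <- read_gene_table(fixture("trout_ighv_directory_synthetic.tsv"))

test_that("directory filters reproduce the published allele totals", {
  d <- build_directory(salmon_tbl, "F_ORF_INFRAME_P")
  expect_equal(nrow(d$entries), 150)
  expect_equal(as.integer(table(d$entries$functionality)[c("F", "ORF", "P")]),
               c(76L, 15L, 59L))
  dt <- build_directory(trout_tbl, "F_ORF_INFRAME_P")
  expect_equal(nrow(dt$entries), 77)
  expect_equal(as.integer(table(dt$entries$functionality)[c("F", "ORF", "P")]),
               c(44L, 11L, 22L))
})

test_that("per-allele functionality is honored for mixed genes", {
  d <- build_directory(salmon_tbl, "F_ORF")
  # the F allele of a gene with a pseudogene *01 still enters
  expect_true("IGHV8-58*02" %in% d$entries$allele_ref)
  expect_false("IGHV8-58*01" %in% d$entries$allele_ref)
})

test_that("the F+ORF set is contained in the extended set", {
  for (tbl in list(salmon_tbl, trout_tbl)) {
    narrow <- build_directory(tbl, "F_ORF")$entries$allele_ref
    wide <- build_directory(tbl, "F_ORF_INFRAME_P")$entries$allele_ref
    expect_true(all(narrow %in% wide))
  }
})

test_that("one-allele-per-gene F+ORF selection yields the 136 tree tips", {
  ns <- nrow(build_directory(salmon_tbl, "F_ORF",
                             one_allele_per_gene = TRUE)$entries)
  nt <- nrow(build_directory(trout_tbl, "F_ORF",
                             one_allele_per_gene = TRUE)$entries)
  expect_equal(ns, 81)
  expect_equal(nt, 55)
  expect_equal(ns + nt, 136)
})

test_that("an empty table yields an empty directory", {
  empty <- salmon_tbl[0, ]
  expect_equal(nrow(build_directory(empty)$entries), 0)
})

test_that("summaries conserve totals over marginals", {
  s <- summarize_gene_table(salmon_tbl, c("subgroup", "locus"))
  expect_equal(s$Total, s$F + s$ORF + s$P + s$unstated)
  expect_equal(attr(s, "grand_total"), sum(s$Total))
  by_locus <- summarize_gene_table(salmon_tbl, "locus")
  expect_equal(sum(by_locus$Total), attr(s, "grand_total"))
  expect_equal(by_locus$Total, c(145, 158))
  expect_error(summarize_gene_table(salmon_tbl, "flavour"), "unknown group_by")
})

test_that("gene mode counts mixed genes once, under best functionality", {
  s <- summarize_gene_table(salmon_tbl, "locus")
  dual <- attr(s, "dual")
  expect_setequal(dual$gene, c("IGHV8-58", "IGHV2D-12"))
  a <- summarize_gene_table(trout_tbl, "locus", unit = "allele")
  expect_equal(sum(a$Total), 77)
})

test_that("directory FASTA serialization round-trips", {
  set.seed(31)
  tbl <- trout_tbl[trout_tbl$subgroup %in% 1:2, ]
  refs <- format_allele_ref(tbl$name, as.integer(tbl$allele))
  seqs <- stats::setNames(vapply(refs, function(x) random_nt(60), ""), refs)
  d <- build_directory(tbl, sequences = seqs)
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_directory_fasta(d, tmp)
  d2 <- read_directory_fasta(tmp)
  cols <- c("allele_ref", "gene", "functionality", "locus_id", "sequence")
  expect_equal(d2$entries[cols], d$entries[cols])
  expect_match(readLines(tmp)[1], "^>IGHV")
})

test_that("malformed FASTA headers are rejected with the field index", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">IGHV1-1*01|Salsal|A|V-REGION", strrep("ACGT", 15)), tmp)
  expect_error(read_directory_fasta(tmp), "field 3")
})

test_that("allele registration is idempotent, numbering, and provisional naming", {
  set.seed(32)
  v1 <- salmigh:::.build_v_ancestor(300)
  tbl <- data.frame(
    name = "IGHV1-1", species = "X", locus_id = "A", chromosome = "c",
    start = 10L, stop = 310L, polarity = "same", subgroup = 1L,
    allele = "01", functionality = "F", in_frame = FALSE,
    stringsAsFactors = FALSE)
  d <- build_directory(tbl, sequences = c("IGHV1-1*01" = v1))

  # identical sequence: no-op
  d1 <- register_allele(d, v1)
  expect_equal(nrow(d1$entries), 1)
  expect_equal(attr(d1, "audit")[[1]]$action, "noop")

  # two substitutions from *01: becomes *02 of the same gene
  v2 <- v1
  substr(v2, 100, 100) <- setdiff(c("A", "C", "G", "T"), substr(v1, 100, 100))[1]
  substr(v2, 200, 200) <- setdiff(c("A", "C", "G", "T"), substr(v1, 200, 200))[1]
  d2 <- register_allele(d, v2, gene = "IGHV1-1")
  expect_true("IGHV1-1*02" %in% d2$entries$allele_ref)

  # unrelated sequence with no gene: provisional S name in a new subgroup
  novel <- salmigh:::.build_v_ancestor(300)
  stopifnot(pairwise_identity(novel, v1) < 0.75)
  d3 <- register_allele(d, novel)
  new_ref <- setdiff(d3$entries$allele_ref, d$entries$allele_ref)
  expect_match(new_ref, "^IGHV[0-9]+S[0-9]+\\*01$")
  expect_equal(parse_gene_name(sub("\\*01$", "", new_ref))$subgroup, 2L)
})
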