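# One desk-scale simulated repertoire shared across the blocks below:
# 2 subgroups x 3 genes, duplicated locus without identical twins, no
# mutations, 30 molecules.
cfg0 <- sim_config(seed = 41, n_subgroups = 2, genes_per_subgroup = 3,
                   identical_duplicates = 0, pseudogene_fraction = 0,
                   orf_fraction = 0, n_reads = 30)
sim0 <- simulate_germline_locus(cfg0)
dir0 <- sim_directory(sim0)
rep0 <- simulate_repertoire(dir0, cfg0)
ann0 <- annotate_repertoire(rep0$reads, dir0)

test_that("mutation-free reads are fully re-annotated", {
  expect_equal(unname(attr(ann0, "summary")["assigned"]), 30L,
               ignore_attr = TRUE)
  expect_equal(ann0$v_call, rep0$truth$v_truth)
  expect_equal(ann0$j_call, rep0$truth$j_truth)
  # every read retaining an identifiable D segment reports the true D
  # (possibly alongside co-longest ties)
  has_d <- rep0$truth$d_retained >= 5
  d_recovered <- mapply(function(dc, dt)
    !is.na(dc) && dt %in% strsplit(dc, ",")[[1]],
    ann0$d_call[has_d], rep0$truth$d_truth[has_d])
  expect_true(all(d_recovered))
  # local alignments may chance-extend past the rearrangement boundary
  # by a base or two, so identity can sit a hair under 1
  expect_true(all(ann0$v_identity >= 0.99))
})

test_that("junctions are cysteine-anchored and frame-consistent", {
  prods <- ann0[ann0$productive, ]
  expect_gt(nrow(prods), 0)
  expect_true(all(nchar(prods$junction) %% 3 == 0))
  expect_true(all(startsWith(prods$junction_aa, "C")))
  expect_false(any(grepl("\\*", prods$junction_aa)))
  expect_equal(nchar(ann0$junction) - 6, nchar(ann0$cdr3))
})

test_that("a D segment trimmed below the minimum length is omitted", {
  e <- dir0$entries
  grp <- vapply(e$gene, function(n) parse_gene_name(n)$group, "")
  vseq <- e$sequence[grp == "V"][1]
  dseq <- e$sequence[grp == "D"][1]
  jseq <- e$sequence[grp == "J"][1]
  # the 3-nt fragment and N bases are chosen so that no 5-nt substring of
  # the junction interior occurs in any directory D-REGION (the documented
  # precondition for an omitted D call)
  read <- paste0(vseq, "A", substr(dseq, 11, 13), "T", jseq)
  ann <- annotate_repertoire(stats::setNames(read, "r3nt"), dir0)
  expect_equal(ann$status, "assigned")
  expect_true(is.na(ann$d_call))
})

test_that("productivity reasons enumerate the failures", {
  expect_true(call_productivity("TGTGCAGCATGG")$productive)
  out <- call_productivity(paste0("TGT", strrep("A", 11)))
  expect_false(out$productive)
  expect_true("OUT_OF_FRAME" %in% out$reasons)
  out <- call_productivity("TGTTAGGCATGG")
  expect_false(out$productive)
  expect_true("STOP_IN_JUNCTION" %in% out$reasons)
})

test_that("random sequences are flagged unassigned, motif-less reads incomplete", {
  set.seed(42)
  junk <- stats::setNames(random_nt(250), "junk")
  ann <- annotate_repertoire(junk, dir0)
  expect_true(ann$status %in% c("unassigned", "incomplete"))
  expect_false(ann$productive)
})

test_that("reads from an identical duplicate pair yield exactly the tied pair", {
  cfg <- sim_config(seed = 43, n_subgroups = 2, genes_per_subgroup = 3,
                    identical_duplicates = 1, pseudogene_fraction = 0,
                    orf_fraction = 0, n_reads = 30)
  sim <- simulate_germline_locus(cfg)
  dir <- sim_directory(sim)
  twin_ref <- sim$truth$allele_ref[sim$truth$twin]
  e <- dir$entries
  pair <- sort(e$allele_ref[e$sequence == e$sequence[e$allele_ref == twin_ref]])
  expect_length(pair, 2)
  rep <- simulate_repertoire(dir, cfg)
  ann <- annotate_repertoire(rep$reads, dir)
  from_twin <- rep$truth$v_truth %in% pair
  got <- vapply(strsplit(ann$v_call, ","), function(x)
    paste(sort(x), collapse = ","), "")
  expect_true(any(from_twin))
  expect_equal(unique(got[from_twin]), paste(pair, collapse = ","))
  expect_true(all(ann$status[from_twin] == "ambiguous"))
  expect_equal(ann$v_call[!from_twin], rep$truth$v_truth[!from_twin])
})

test_that("reverse-complemented reads are oriented and annotated", {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rep0$reads[[1]])))
  ann <- annotate_repertoire(stats::setNames(rc, "rc1"), dir0)
  expect_true(ann$rev_comp)
  expect_equal(ann$v_call, rep0$truth$v_truth[1])
  expect_equal(ann$junction, ann0$junction[1])
})

test_that("UMI groups collapse to majority-vote consensus molecules", {
  out <- dedup_umi(c(a = "ACGTACGT", b = "ACGTACGT", c = "ACGTACGT"),
                   rep("AAAA", 3))
  expect_equal(nrow(out), 1)
  expect_equal(out$size, 3)
  expect_equal(out$sequence, "ACGTACGT")
  # 2:1 disagreement at one column keeps the majority base
  out <- dedup_umi(c("ACGT", "ACTT", "ACTT"), rep("CCCC", 3))
  expect_equal(out$sequence, "ACTT")
  # all-distinct UMIs: identity transform
  out <- dedup_umi(c("AAAA", "CCCC"), c("GGGG", "TTTT"))
  expect_equal(nrow(out), 2)
  expect_equal(sort(out$sequence), c("AAAA", "CCCC"))
  expect_error(dedup_umi(c("A", "C"), c("AA", "A")), "ragged")
})

test_that("usage percentages sum to 100 with fractional ties", {
  u <- usage_table(ann0)
  expect_equal(sum(u$pct), 100, tolerance = 1e-9)
  expect_equal(attr(u, "n_productive"), sum(ann0$productive))
  # records tied between two genes split 50/50
  recs <- data.frame(
    sequence_id = c("r1", "r2"),
    v_call = rep("IGHV1-1*01,IGHV1D-1*01", 2),
    j_call = "IGHJ1*01", cdr3 = "TGTGCA", junction = "TGTTGTGCATGG",
    productive = TRUE, locus = "ambiguous", stringsAsFactors = FALSE)
  u2 <- usage_table(recs)
  expect_equal(u2$pct, c(50, 50))
  expect_error(usage_table(recs[0, ]), "no productive")
})

test_that("clonotype counts sum to the productive record count", {
  cl <- aggregate_clonotypes(ann0)
  expect_equal(sum(cl$count), sum(ann0$productive))
  one <- ann0[which(ann0$productive)[1], ]
  expect_equal(nrow(aggregate_clonotypes(one)), 1)
})

test_that("rearrangements serialize to an AIRR-style TSV", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_airr_tsv(ann0, tmp)
  back <- utils::read.delim(tmp)
  expect_equal(nrow(back), nrow(ann0))
  expect_true(all(c("sequence_id", "v_call", "junction_aa", "productive",
                    "duplicate_count") %in% names(back)))
})
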