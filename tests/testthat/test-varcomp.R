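# exact Fisher p by hypergeometric enumeration (two-sided, by probability
# ordering) — independent of stats::fisher.test
oracle_fisher_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("SNP effects follow the genetic code in the gene frame", {
  seqs <- c(geneA = "ATGGGACTT")  # M G L
  cls <- c(geneA = "functional")
  vars <- data.frame(gene = "geneA", position = c(6L, 4L, 9L),
                     ref = c("A", "G", "T"), alt = c("G", "T", "A"),
                     stringsAsFactors = FALSE)
  tl <- tally_variants(vars, seqs, cls)
  # GGA -> GGG third-position: silent; GGA -> TGA first-position: non-silent
  expect_equal(tl$per_variant$effect, c("SILENT", "NON_SILENT", "SILENT"))
  expect_equal(tl$per_gene$snp, 3L)
  expect_equal(tl$per_gene$ns, 1L)
})

test_that("pseudogene variants count as SNPs but never as non-silent", {
  seqs <- c(g1 = "ATGGGACTT", g2 = "ATGGGACTT")
  cls <- c(g1 = "functional", g2 = "pseudogene")
  vars <- data.frame(gene = c("g1", "g2", "g2"), position = c(4L, 4L, 2L),
                     ref = c("G", "G", "TG"), alt = c("T", "T", "T"),
                     stringsAsFactors = FALSE)
  tl <- tally_variants(vars, seqs, cls)
  expect_equal(tl$per_variant$kind, c("SNP", "SNP", "INDEL"))
  expect_true(is.na(tl$per_variant$effect[2]))
  pg <- tl$per_gene[tl$per_gene$gene == "g2", ]
  expect_equal(pg$snp, 1L)
  expect_equal(pg$ns, 0L)
  expect_equal(pg$indel, 1L)
})

test_that("variant bounds and reference bases are checked", {
  seqs <- c(g = "ATGGGA"); cls <- c(g = "functional")
  expect_error(tally_variants(
    data.frame(gene = "g", position = 9L, ref = "A", alt = "G"), seqs, cls),
    "outside")
  expect_error(tally_variants(
    data.frame(gene = "g", position = 1L, ref = "C", alt = "G"), seqs, cls),
    "mismatch")
  expect_error(tally_variants(
    data.frame(gene = "zz", position = 1L, ref = "A", alt = "G"), seqs, cls),
    "unknown gene")
  empty <- tally_variants(
    data.frame(gene = character(), position = integer(),
               ref = character(), alt = character()), seqs, cls)
  expect_equal(nrow(empty$per_gene), 0)
})

test_that("the packaged variant table reproduces the printed class totals", {
  vs <- read_variant_summary(fixture("trout_ighv_variants.tsv"))
  tot <- variant_class_totals(vs)
  pick <- function(chrom, cls) tot[tot$chromosome == chrom & tot$class == cls, ]
  expect_equal(pick("Chr13", "functional")[, c("snp", "ns", "indel")],
               data.frame(snp = 67L, ns = 40L, indel = 1L),
               ignore_attr = TRUE)
  expect_equal(pick("Chr12", "functional")[, c("snp", "ns", "indel")],
               data.frame(snp = 23L, ns = 13L, indel = 0L),
               ignore_attr = TRUE)
  expect_equal(pick("Chr13", "pseudogene")$snp, 41L)
  expect_equal(pick("Chr13", "pseudogene")$indel, 3L)
  expect_equal(pick("Chr13", "functional")$n_genes, 29L)
  expect_equal(pick("Chr12", "pseudogene")$n_genes, 51L)
})

test_that("non-silent proportions compare via Fisher and chi-square", {
  tab <- rbind(c(40, 27), c(13, 10))
  res <- compare_ns_proportions(tab)
  expect_false(res$significant)
  expect_gt(res$fisher_p, 0.05)
  expect_equal(res$fisher_p, oracle_fisher_p(tab), tolerance = 1e-10)
  expect_equal(compare_ns_proportions(rbind(c(10, 10), c(5, 5)))$fisher_p, 1)
  expect_error(compare_ns_proportions(rbind(c(0, 0), c(5, 5))),
               "degenerate margin")
})

test_that("a two-taxon UPGMA tree splits the distance evenly", {
  d <- matrix(c(0, 0.2, 0.2, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  tr <- upgma_tree(d)
  expect_equal(sort(tr$edge.length), c(0.1, 0.1))
  expect_true(is_ultrametric_tree(tr))
})

test_that("UPGMA agrees with a brute-force oracle and stays ultrametric", {
  set.seed(61)
  for (i in 1:30) {
    n <- sample(3:6, 1)
    d <- as.matrix(stats::dist(matrix(stats::rnorm(n * 4), n)))
    dimnames(d) <- list(letters[1:n], letters[1:n])
    tr <- upgma_tree(d)
    expect_true(is_ultrametric_tree(tr))
    coph <- as.matrix(stats::cophenetic(tr))[letters[1:n], letters[1:n]]
    expect_equal(coph, oracle_upgma_cophenetic(d), tolerance = 1e-9)
  }
})

test_that("bootstrap supports are reproducible and in [0, 100]", {
  set.seed(62)
  aln <- stats::setNames(vapply(1:5, function(i) random_nt(120), ""),
                         paste0("t", 1:5))
  # relate t2 to t1 so the tree has structure
  aln[2] <- paste0(substr(aln[1], 1, 100), substr(aln[2], 101, 120))
  d <- aligned_distance(aln)
  t1 <- upgma_tree(d, alignment = aln, n_replicates = 100, seed = 9)
  t2 <- upgma_tree(d, alignment = aln, n_replicates = 100, seed = 9)
  expect_identical(t1$node.label, t2$node.label)
  expect_true(all(t1$node.label >= 0 & t1$node.label <= 100))
  nwk <- ape::write.tree(t1)
  expect_match(nwk, "^\\(")
  expect_error(upgma_tree(d[, c(2:5, 1)]), "symmetric")
})
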