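test_that("the generator is deterministic under its seed", {
  cfg <- sim_config(seed = 51, n_subgroups = 2, genes_per_subgroup = 3,
                    n_reads = 10)
  s1 <- simulate_germline_locus(cfg)
  s2 <- simulate_germline_locus(cfg)
  expect_identical(s1$sequences, s2$sequences)
  expect_identical(s1$gene_table, s2$gene_table)
  d <- sim_directory(s1)
  r1 <- simulate_repertoire(d, cfg)
  r2 <- simulate_repertoire(d, cfg)
  expect_identical(r1$reads, r2$reads)
  expect_identical(r1$truth, r2$truth)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(), "seed")
  expect_error(sim_config(seed = 1, between_ceiling = 0.8), "0.75")
  expect_error(sim_config(seed = 1, pseudogene_fraction = 0.7,
                          orf_fraction = 0.5), "exceed")
  expect_error(sim_config(seed = 1, v_region_length = 301), "multiple of 3")
})

test_that("planted subgroup structure is recovered by re-clustering", {
  cfg <- sim_config(seed = 52, n_subgroups = 3, genes_per_subgroup = 4,
                    n_reads = 1)
  sim <- simulate_germline_locus(cfg)
  seqs <- stats::setNames(sim$v_regions[sim$truth$allele_ref],
                          sim$truth$allele_ref)
  cs <- cluster_subgroups(identity_matrix(seqs))
  tab <- table(cs$assignment, sim$truth$subgroup)
  expect_equal(max(cs$assignment), 3)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("planted functionality labels are recovered exactly", {
  cfg <- sim_config(seed = 53, n_reads = 1)
  sim <- simulate_germline_locus(cfg)
  called <- vapply(sim$truth$allele_ref, function(ref)
    classify_functionality(sim$v_regions[[ref]],
                           leader_nt = sim$leaders[[ref]],
                           flank_3p = sim$flanks_3p[[ref]])$value, "")
  expect_equal(unname(called), sim$truth$functionality)
  in_frame_called <- vapply(sim$truth$allele_ref, function(ref)
    isTRUE(classify_functionality(sim$v_regions[[ref]])$in_frame), TRUE)
  p_idx <- sim$truth$functionality == "P"
  expect_equal(unname(in_frame_called[p_idx]), sim$truth$in_frame[p_idx])
})

test_that("zero pseudogene fraction leaves only F and ORF alleles", {
  cfg <- sim_config(seed = 54, pseudogene_fraction = 0, n_reads = 1)
  sim <- simulate_germline_locus(cfg)
  called <- vapply(sim$truth$allele_ref, function(ref)
    classify_functionality(sim$v_regions[[ref]],
                           flank_3p = sim$flanks_3p[[ref]])$value, "")
  expect_true(all(called %in% c("F", "ORF")))
})

test_that("weighted V sampling reproduces the configured skew", {
  cfg <- sim_config(seed = 55, n_subgroups = 2, genes_per_subgroup = 1,
                    duplicate_locus = FALSE, pseudogene_fraction = 0,
                    orf_fraction = 0, n_dispersed_d = 0, n_reads = 150)
  sim <- simulate_germline_locus(cfg)
  dir <- sim_directory(sim)
  grp <- vapply(dir$entries$gene, function(n) parse_gene_name(n)$group, "")
  vs <- dir$entries$allele_ref[grp == "V"]
  cfg$v_weights <- stats::setNames(c(0.7, 0.3), vs)
  rep <- simulate_repertoire(dir, cfg)
  p_hat <- mean(rep$truth$v_truth == vs[1])
  # within 3 binomial standard errors of 0.7
  expect_lt(abs(p_hat - 0.7), 3 * sqrt(0.7 * 0.3 / 150))
})

test_that("locus-B copies diverge by the configured amount and carry D names", {
  cfg <- sim_config(seed = 56, identical_duplicates = 0, n_reads = 1)
  sim <- simulate_germline_locus(cfg)
  a <- sim$truth[sim$truth$locus_id == "A", ]
  b <- sim$truth[sim$truth$locus_id == "B", ]
  expect_true(all(grepl("D-", b$name)))
  ident <- vapply(seq_len(nrow(a)), function(i) pairwise_identity(
    sim$v_regions[[a$allele_ref[i]]], sim$v_regions[[b$allele_ref[i]]]),
    numeric(1))
  expect_true(all(ident > 0.9))
  expect_true(all(ident < 1))
})
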