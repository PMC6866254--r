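toy_locus <- function(groups, orientation = "FWD", locus_id = "A",
                      isotypes = NULL, tau = NULL, subgroups = NULL,
                      c_override = NULL) {
  n <- length(groups)
  g <- data.frame(id = sprintf("g%02d", seq_len(n)), group = groups,
                  start = 1000L + seq_len(n) * 1000L,
                  stop = 1000L + seq_len(n) * 1000L + 99L,
                  stringsAsFactors = FALSE)
  g$isotype <- if (is.null(isotypes)) NA_character_ else isotypes
  g$tau_series <- if (is.null(tau)) NA_integer_ else tau
  g$subgroup <- if (is.null(subgroups)) NA_integer_ else subgroups
  if (!is.null(c_override)) g$c_override <- c_override
  igh_locus("X", locus_id, "chr", orientation,
            span = c(0L, 10000L + n * 1000L), genes = g)
}

test_that("genes order by coordinate according to locus orientation", {
  fwd <- toy_locus(c("V", "V"))
  expect_equal(order_genes(fwd)$genes$start, c(2000L, 3000L))
  rev <- toy_locus(c("V", "V"), orientation = "REV")
  expect_equal(order_genes(rev)$genes$start, c(3000L, 2000L))
  out <- toy_locus(c("V", "V"))
  out$genes$start[1] <- -5L
  expect_error(order_genes(out), "outside locus span")
})

test_that("D/J genes associate with the nearest downstream cluster", {
  # V V D D J C(T2) D J C(M) C(Delta)
  lc <- toy_locus(c("V", "V", "D", "D", "J", "C", "D", "J", "C", "C"),
                  isotypes = c(NA, NA, NA, NA, NA, "T", NA, NA, "M", "Delta"),
                  tau = c(NA, NA, NA, NA, NA, 2L, rep(NA, 4)),
                  subgroups = c(1L, 1L, rep(NA, 8)))
  assoc <- associate_dj_to_c(order_genes(lc))
  expect_equal(assoc$tag[assoc$id %in% c("g03", "g04", "g05")],
               rep("T2", 3))
  expect_true(all(is.na(assoc$tag[assoc$id %in% c("g07", "g08")])))
  expect_equal(assoc$assoc_c[assoc$id == "g07"], "g09")
  members <- attr(assoc, "members")
  expect_equal(members$g06, c("g03", "g04", "g05"))
})

test_that("a D gene flanked by V genes is dispersed; a J gene never is", {
  lc <- toy_locus(c("V", "D", "V", "C"), isotypes = c(NA, NA, NA, "M"),
                  subgroups = c(1L, NA, 1L, NA))
  assoc <- associate_dj_to_c(order_genes(lc))
  expect_equal(assoc$assoc_c[assoc$id == "g02"], "DISPERSED")
  lc_j <- toy_locus(c("V", "J", "V", "C"), isotypes = c(NA, NA, NA, "M"),
                    subgroups = c(1L, NA, 1L, NA))
  expect_error(associate_dj_to_c(order_genes(lc_j)), "never dispersed")
})

test_that("the cluster override forces an association", {
  # D genes printed downstream of their tau gene
  lc <- toy_locus(c("C", "D", "D", "C"),
                  isotypes = c("T", NA, NA, "M"),
                  tau = c(3L, NA, NA, NA),
                  c_override = c(NA, "g01", "g01", NA))
  assoc <- associate_dj_to_c(order_genes(lc))
  expect_equal(assoc$assoc_c[assoc$group == "D"], c("g01", "g01"))
  expect_equal(assoc$tag[assoc$group == "D"], c("T3", "T3"))
})

test_that("positional names count 3' to 5' and honor the locus-B suffix", {
  lc <- toy_locus(c("V", "V", "V", "D", "J", "C", "C"),
                  isotypes = c(rep(NA, 5), "M", "Delta"),
                  subgroups = c(2L, 1L, 2L, rep(NA, 4)))
  tbl <- assign_positional_names(order_genes(lc))
  expect_equal(tbl$name[1:3], c("IGHV2-3", "IGHV1-2", "IGHV2-1"))
  lcB <- lc; lcB$locus_id <- "B"
  tblB <- assign_positional_names(order_genes(lcB))
  expect_equal(tblB$name[1:3], c("IGHV2D-3", "IGHV1D-2", "IGHV2D-1"))
  expect_equal(tblB$name[tblB$id == "g06"], "IGHMD")
})

test_that("five D genes upstream of tau series 4 are numbered IGHD1T4..IGHD5T4", {
  lc <- toy_locus(c(rep("D", 5), "J", "C", "C", "C"),
                  isotypes = c(rep(NA, 6), "T", "M", "Delta"),
                  tau = c(rep(NA, 6), 4L, NA, NA))
  tbl <- assign_positional_names(order_genes(lc))
  expect_equal(tbl$name[1:5], paste0("IGHD", 1:5, "T4"))
  expect_equal(tbl$name[6], "IGHJ1T4")
})

test_that("missing V subgroups are an error", {
  lc <- toy_locus(c("V", "C"), isotypes = c(NA, "M"))
  expect_error(assign_positional_names(order_genes(lc)), "missing subgroup")
})

test_that("printed trout positions are monotone in distance from the 3' cluster", {
  vs <- read_variant_summary(fixture("trout_ighv_variants.tsv"))
  pos <- vapply(vs$name, function(n) parse_gene_name(n)$position, 1L)
  for (chrom in c("Chr12", "Chr13")) {
    idx <- vs$chromosome == chrom
    # both trout loci are FWD with the clusters at the high-coordinate end
    rk <- v_distance_rank(vs$start[idx], "FWD")
    printed <- pos[idx]
    expect_true(all(diff(printed[order(rk)]) >= 0), info = chrom)
    expect_gt(cor(rk, printed, method = "spearman"), 0.999)
  }
  # the locus-B example pair: position 1 lies closer to the cluster than 76
  expect_lt(vs$start[vs$name == "IGHV6D-76"], vs$start[vs$name == "IGHV16D-1"])
})

test_that("positional numbers are a gap-free permutation on simulated loci", {
  cfg <- sim_config(seed = 21, n_subgroups = 2, genes_per_subgroup = 3,
                    n_reads = 1)
  sim <- simulate_germline_locus(cfg)
  for (lid in c("A", "B")) {
    tbl <- sim$gene_table[sim$gene_table$locus_id == lid, ]
    vpos <- vapply(tbl$name[grepl("^IGHV", tbl$name)],
                   function(n) parse_gene_name(n)$position, 1L)
    expect_setequal(vpos, seq_along(vpos))
    # distance rank and position agree exactly
    lc <- sim$loci[[lid]]
    vg <- lc$genes[lc$genes$group == "V", ]
    rk <- v_distance_rank(vg$start, lc$orientation)
    tbl_v <- tbl[match(vg$id, tbl$id), ]
    pos <- vapply(tbl_v$name, function(n) parse_gene_name(n)$position, 1L)
    expect_equal(cor(rk, pos, method = "spearman"), 1)
  }
})

test_that("GFF3 emission writes one feature per gene with proper strand", {
  lc <- toy_locus(c("V", "C"), isotypes = c(NA, "M"), subgroups = c(1L, NA),
                  orientation = "REV")
  tbl <- assign_positional_names(order_genes(lc))
  tmp <- withr::local_tempfile(fileext = ".gff3")
  write_locus_gff3(tbl, tmp, orientation = "REV")
  lines <- readLines(tmp)
  expect_equal(lines[1], "##gff-version 3")
  expect_length(lines, 3)
  v_line <- grep("V_gene_segment", lines, value = TRUE)
  expect_length(v_line, 1)
  expect_match(v_line, "\t-\t")
})
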