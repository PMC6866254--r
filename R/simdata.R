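#' Synthetic duplicated-locus and repertoire simulator
#'
#' Generates germline IGH loci with controlled subgroup structure
#' (within-subgroup identity above, between-subgroup identity below the 75%
#' classification threshold), a duplicated locus B as a diverged copy of
#' locus A, planted functionality defects (premature stops and frameshifts
#' for pseudogenes, recombination-signal defects for ORF genes), and
#' V-D-J rearranged reads with exonuclease trimming, untemplated N
#' additions, uniform point mutations and optional UMIs. Every gene and
#' every read carries a ground-truth record, and all output is
#' deterministic under the configured seed.
#'
#' @name simdata
NULL

.codons_all <- local({
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
})
.codons_stop <- c("TAA", "TAG", "TGA")
.codons_safe <- setdiff(.codons_all, .codons_stop)
# stub codons avoid cysteine (so the 2nd-CYS codon stays the last in-frame
# TGY of a V gene) and stops
.codons_stub <- setdiff(.codons_safe, c("TGT", "TGC"))

#' Simulator configuration
#'
#' Defaults describe a desk-scale duplicated locus: identity structure per
#' the 75% subgroup rule (within-subgroup target 0.85, between-subgroup
#' ceiling 0.65), a locus-B copy at 2% per-base divergence with one
#' identical twin pair, a 300-nt V-REGION, V/D/J trimming of 0-5 / 0-6 per
#' side / 0-5 nt, geometric N-addition lengths with mean 3, and no somatic
#' mutation unless requested.
#'
#' @param n_subgroups number of V subgroups.
#' @param genes_per_subgroup V genes per subgroup (per locus A).
#' @param within_identity target identity of a subgroup member to its
#'   subgroup ancestor.
#' @param between_ceiling maximum allowed pairwise identity between
#'   subgroup ancestors.
#' @param duplicate_locus also emit locus B, a diverged copy of locus A.
#' @param duplicate_divergence per-base divergence of locus-B gene copies.
#' @param identical_duplicates number of locus-B V genes kept sequence-
#'   identical to their locus-A twin (duplicated genes with identical
#'   V-REGIONs exist in the real loci and force ambiguous calls).
#' @param pseudogene_fraction,orf_fraction fractions of V genes planted as
#'   pseudogenes / ORF.
#' @param v_region_length V-REGION core length in nt (multiple of 3,
#'   246-312).
#' @param n_dispersed_d dispersed diversity genes placed among the V genes.
#' @param trim_v,trim_d,trim_j trimming ranges (nt) for the V 3' end, each
#'   D side, and the J 5' end.
#' @param n_mean mean of the geometric N-addition length distribution.
#' @param mutation_rate uniform per-base substitution rate on reads.
#' @param n_reads reads per simulated repertoire.
#' @param v_weights optional named sampling weights over V alleles.
#' @param umi attach UMIs; `umi_dup` reads are emitted per molecule.
#' @param umi_length,umi_dup UMI length and per-molecule duplication factor.
#' @param seed integer seed (required; all randomness derives from it).
#' @return an `igh_sim_config` list.
#' @export
sim_config <- function(n_subgroups = 3, genes_per_subgroup = 4,
                       within_identity = 0.85, between_ceiling = 0.65,
                       duplicate_locus = TRUE, duplicate_divergence = 0.02,
                       identical_duplicates = 1,
                       pseudogene_fraction = 0.25, orf_fraction = 0.125,
                       v_region_length = 300, n_dispersed_d = 2,
                       trim_v = 0:5, trim_d = 0:6, trim_j = 0:5,
                       n_mean = 3, mutation_rate = 0, n_reads = 200,
                       v_weights = NULL, umi = FALSE, umi_length = 8,
                       umi_dup = 2, seed) {
  if (missing(seed)) stop("sim_config requires an explicit seed", call. = FALSE)
  if (!(between_ceiling < 0.75 && 0.75 < within_identity))
    stop("need between_ceiling < 0.75 < within_identity", call. = FALSE)
  if (pseudogene_fraction + orf_fraction > 1)
    stop("functionality fractions exceed 1", call. = FALSE)
  if (v_region_length %% 3 != 0 || v_region_length < 246 || v_region_length > 312)
    stop("v_region_length must be a multiple of 3 in 246-312", call. = FALSE)
  structure(as.list(environment()), class = "igh_sim_config")
}

.sample_codons <- function(n, pool = .codons_safe)
  paste(sample(pool, n, replace = TRUE), collapse = "")

# anchor codon positions (1-based codon index) for a V core of n_aa codons
.v_anchors <- function(n_aa) {
  c1 <- min(12L, n_aa - 82L)
  c2 <- n_aa - 82L - c1
  list(c1 = c1, c2 = c2,
       cys23 = 23L, trp = 29L + c1, hydro = 67L + c1 + c2, cys104 = n_aa)
}

.build_v_ancestor <- function(len) {
  n_aa <- len %/% 3L
  a <- .v_anchors(n_aa)
  codons <- sample(.codons_safe, n_aa, replace = TRUE)
  codons[a$cys23] <- "TGC"
  codons[a$trp] <- "TGG"
  codons[a$hydro] <- "GTG"
  codons[a$cys104] <- "TGC"
  paste(codons, collapse = "")
}

# substitute exactly k positions chosen outside the anchor codons, then
# repair any stop codons the substitutions created
.mutate_coding <- function(seq, rate, anchors, protect_codons = integer()) {
  n <- nchar(seq)
  bases <- strsplit(seq, "")[[1]]
  protected <- unlist(lapply(c(anchors, protect_codons),
                             function(cd) (3L * cd - 2L):(3L * cd)))
  eligible <- setdiff(seq_len(n), protected)
  k <- min(round(n * rate), length(eligible))
  if (k > 0) {
    pos <- sample(eligible, k)
    for (p in pos)
      bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1)
  }
  out <- paste(bases, collapse = "")
  .repair_stops(out, protect_codons)
}

.repair_stops <- function(seq, protect_codons = integer()) {
  n_aa <- nchar(seq) %/% 3L
  codons <- substring(seq, 3L * seq_len(n_aa) - 2L, 3L * seq_len(n_aa))
  bad <- which(codons %in% .codons_stop)
  bad <- setdiff(bad, protect_codons)
  for (i in bad) codons[i] <- sub("^TA", "TC", sub("^TGA$", "TCA", codons[i]))
  # partial trailing bases survive untouched
  tail_nt <- substring(seq, 3L * n_aa + 1L)
  paste0(paste(codons, collapse = ""), tail_nt)
}

.random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

.make_rss_flank <- function(spacer = 23L, defect = FALSE) {
  hept <- if (defect) "CTCAGTG" else "CACAGTG"
  repeat {
    fl <- paste0(.random_nt(4L), hept, .random_nt(spacer), "ACAAAAACC",
                 .random_nt(4L))
    hit <- find_rss(fl, spacer)
    # a defective flank must scan as defective (no chance rescue by a
    # spurious seed in the random spacer); an intact one must scan clean
    if (defect == is.null(hit)) return(fl)
  }
}

.kmers <- function(s, k = 5L) {
  n <- nchar(s)
  if (n < k) return(character())
  substring(s, seq_len(n - k + 1L), k:n)
}

# J-REGION: 3 stub codons (no W/F/stop/cys), the W-G-x-G motif, then a tail;
# regenerated until the motif is unique at the expected offset
.build_j_region <- function() {
  repeat {
    stub_pool <- setdiff(.codons_stub, c("TGG", "TTT", "TTC"))
    j <- paste0(.sample_codons(3L, stub_pool), "TGGGGC",
                sample(.codons_safe, 1), "GGC", .sample_codons(5L, .codons_safe))
    if (identical(find_wgxg(j), 10L)) return(j)
  }
}

#' Locate the W/F-G-x-G motif in a J-REGION
#'
#' The conserved J-REGION motif whose tryptophan/phenylalanine codon is
#' unique-numbering position 118, the 3' boundary of the junction.
#'
#' @param jseq J-REGION nucleotide sequence.
#' @return 1-based offset of the W/F codon, or `NA` when absent.
#' @export
find_wgxg <- function(jseq) {
  n <- nchar(jseq)
  if (n < 12L) return(NA_integer_)
  for (s in seq_len(n - 11L)) {
    aa <- translate_nt(substr(jseq, s, s + 11L))
    if (substr(aa, 1, 1) %in% c("W", "F") && substr(aa, 2, 2) == "G" &&
        substr(aa, 4, 4) == "G")
      return(s)
  }
  NA_integer_
}

#' Simulate a duplicated germline locus
#'
#' Subgroup ancestors are drawn by rejection sampling until every ancestor
#' pair sits at or below the between-subgroup identity ceiling; members are
#' mutated copies of their ancestor at the within-subgroup target.
#' Functionality defects are planted per the configured fractions
#' (premature stop or 1-nt deletion for pseudogenes, a broken
#' recombination-signal heptamer for ORF genes). Locus B, when enabled, is
#' a per-gene diverged copy of locus A with the same planted classes; the
#' first `identical_duplicates` functional genes stay sequence-identical to
#' their twin. Each locus carries one tau D-J-C cluster and one mu/delta
#' cluster, plus dispersed D genes among the V genes. Locus A is
#' reverse-oriented, locus B forward, mirroring the prototype loci.
#'
#' @param config an [sim_config()].
#' @return a list of class `igh_sim_locus`: `config`, `loci` (named list of
#'   [igh_locus()]), `gene_table` (assigned names, one row per gene),
#'   `sequences` (named vector keyed by allele reference: full V gene
#'   sequences including the 6-nt germline CDR3 stub, D-REGIONs,
#'   J-REGIONs), `v_regions` (V-REGION cores for identity/functionality
#'   work), `flanks_3p`, `leaders`, and `truth` (planted subgroup,
#'   functionality, in-frame flag, defect and name per gene).
#' @export
simulate_germline_locus <- function(config) {
  stopifnot(inherits(config, "igh_sim_config"))
  set.seed(config$seed)
  len <- config$v_region_length
  n_aa <- len %/% 3L
  anc_info <- .v_anchors(n_aa)
  anchor_codons <- c(anc_info$cys23, anc_info$trp, anc_info$hydro, anc_info$cys104)

  # --- subgroup ancestors (rejection sampling against the ceiling) -------
  ancestors <- character(config$n_subgroups)
  tries <- 0L
  for (s in seq_len(config$n_subgroups)) {
    repeat {
      tries <- tries + 1L
      if (tries > 200L * config$n_subgroups)
        stop("rejection sampling exceeded iteration cap; ",
             "between_ceiling too tight", call. = FALSE)
      cand <- .build_v_ancestor(len)
      ok <- TRUE
      for (p in seq_len(s - 1L))
        if (pairwise_identity(cand, ancestors[p]) > config$between_ceiling) {
          ok <- FALSE
          break
        }
      if (ok) { ancestors[s] <- cand; break }
    }
  }

  # --- locus A members with planted functionality -------------------------
  n_genes <- config$n_subgroups * config$genes_per_subgroup
  classes <- rep("F", n_genes)
  n_p <- round(config$pseudogene_fraction * n_genes)
  n_orf <- round(config$orf_fraction * n_genes)
  if (n_p + n_orf > 0)
    classes[sample(n_genes, n_p + n_orf)] <-
      c(rep("P", n_p), rep("ORF", n_orf))
  genes <- vector("list", n_genes)
  gi <- 0L
  for (s in seq_len(config$n_subgroups)) {
    for (m in seq_len(config$genes_per_subgroup)) {
      gi <- gi + 1L
      core <- if (m == 1L) ancestors[s] else
        .mutate_coding(ancestors[s], 1 - config$within_identity, anchor_codons)
      cls <- classes[gi]
      defect <- "none"
      in_frame <- NA
      if (cls == "P") {
        if (gi %% 2L == 0L) {
          stop_at <- sample(setdiff(30:90, anchor_codons), 1)
          core <- paste0(substr(core, 1, 3 * stop_at - 3), "TAA",
                         substring(core, 3 * stop_at + 1))
          defect <- "STOP_CODON"
          in_frame <- TRUE
        } else {
          cut <- sample(seq(40L, nchar(core) - 40L), 1)
          core <- paste0(substr(core, 1, cut - 1L), substring(core, cut + 1L))
          defect <- "FRAMESHIFT"
          in_frame <- FALSE
        }
      }
      stub <- .sample_codons(2L, .codons_stub)
      genes[[gi]] <- list(
        id = sprintf("VA%02d", gi), subgroup = s, class = cls,
        defect = defect, in_frame = in_frame,
        core = core, stub = stub, gene_nt = paste0(core, stub),
        flank = .make_rss_flank(23L, defect = cls == "ORF"),
        leader = paste0("ATG", .sample_codons(5L, .codons_safe)),
        stop_codon = if (defect == "STOP_CODON") stop_at else NA_integer_)
    }
  }

  # --- locus B: diverged copies -------------------------------------------
  genes_b <- list()
  if (config$duplicate_locus) {
    f_idx <- which(vapply(genes, function(g) g$class == "F", TRUE))
    twins <- f_idx[seq_len(min(config$identical_duplicates, length(f_idx)))]
    for (gi in seq_along(genes)) {
      g <- genes[[gi]]
      if (gi %in% twins) {
        core <- g$core; stub <- g$stub
      } else {
        protect <- if (!is.na(g$stop_codon)) g$stop_codon else integer()
        full <- .mutate_coding(paste0(g$core, g$stub),
                               config$duplicate_divergence,
                               if (g$defect == "FRAMESHIFT") integer() else anchor_codons,
                               protect)
        core <- substr(full, 1, nchar(g$core))
        stub <- substring(full, nchar(g$core) + 1L)
        stub <- .repair_stub(stub)
      }
      gb <- g
      gb$id <- sub("^VA", "VB", g$id)
      gb$core <- core; gb$stub <- stub; gb$gene_nt <- paste0(core, stub)
      gb$twin <- gi %in% twins
      gb$flank <- .make_rss_flank(23L, defect = g$class == "ORF")
      genes_b[[length(genes_b) + 1L]] <- gb
    }
  }

  # --- D and J germline elements ------------------------------------------
  # every D gene (across both loci) gets its own 5-mer-disjoint sequence so
  # that the longest-substring D search has a unique answer
  n_d_cluster <- 3L
  n_loci <- if (config$duplicate_locus) 2L else 1L
  n_d_per_locus <- n_d_cluster + 2L + config$n_dispersed_d
  n_j_per_locus <- 3L
  d_pool <- character()
  draw_d <- function() {
    repeat {
      cand <- .random_nt(18L)
      if (!any(.kmers(cand) %in% unlist(lapply(d_pool, .kmers)))) return(cand)
    }
  }
  for (i in seq_len(n_d_per_locus * n_loci)) d_pool <- c(d_pool, draw_d())
  j_pool <- vapply(seq_len(n_j_per_locus * n_loci),
                   function(i) .build_j_region(), "")

  # --- assemble loci -------------------------------------------------------
  assemble <- function(genes, locus_id, chromosome, orientation) {
    nv <- length(genes)
    v_order <- sample(nv)   # biological 5'->3' order of the V genes
    rows <- list()
    # dispersed D genes at fixed slots among the V block
    disp_slots <- if (config$n_dispersed_d > 0)
      sort(sample(nv - 1L, config$n_dispersed_d)) else integer()
    slot <- 0L
    push <- function(id, group, width = 300L, ...) {
      slot <<- slot + 1L
      rows[[length(rows) + 1L]] <<- data.frame(
        id = id, group = group, slot = slot, width = width, ...,
        stringsAsFactors = FALSE)
    }
    for (k in seq_len(nv)) {
      g <- genes[[v_order[k]]]
      push(g$id, "V", width = nchar(g$gene_nt), subgroup = g$subgroup,
           functionality = g$class, in_frame = isTRUE(g$in_frame))
      if (k %in% disp_slots)
        push(paste0("Ddisp", match(k, disp_slots), locus_id), "D", width = 18L,
             subgroup = NA, functionality = "F", in_frame = FALSE)
    }
    # tau cluster: D D J C[T1]; mu cluster: D D D J J C[M] C[Delta]
    push(paste0("Dt1", locus_id), "D", 18L, subgroup = NA, functionality = "F",
         in_frame = FALSE)
    push(paste0("Dt2", locus_id), "D", 18L, subgroup = NA, functionality = "F",
         in_frame = FALSE)
    push(paste0("Jt1", locus_id), "J", 36L, subgroup = NA, functionality = "F",
         in_frame = FALSE)
    push(paste0("Ct", locus_id), "C", 1500L, subgroup = NA, functionality = "F",
         in_frame = FALSE)
    for (i in seq_len(n_d_cluster))
      push(paste0("Dm", i, locus_id), "D", 18L, subgroup = NA,
           functionality = "F", in_frame = FALSE)
    for (i in 1:2)
      push(paste0("Jm", i, locus_id), "J", 36L, subgroup = NA,
           functionality = "F", in_frame = FALSE)
    push(paste0("Cm", locus_id), "C", 2000L, subgroup = NA, functionality = "F",
         in_frame = FALSE)
    push(paste0("Cd", locus_id), "C", 3000L, subgroup = NA, functionality = "F",
         in_frame = FALSE)
    df <- do.call(rbind, rows)
    df$isotype <- NA_character_
    df$tau_series <- NA_integer_
    df$isotype[df$id == paste0("Ct", locus_id)] <- "T"
    df$tau_series[df$id == paste0("Ct", locus_id)] <- 1L
    df$isotype[df$id == paste0("Cm", locus_id)] <- "M"
    df$isotype[df$id == paste0("Cd", locus_id)] <- "Delta"
    # coordinates: 4-kb slots; REV locus descends along the chromosome
    base <- 1000000L
    if (orientation == "FWD") {
      df$start <- base + df$slot * 4000L
    } else {
      df$start <- base - df$slot * 4000L
    }
    df$stop <- df$start + df$width - 1L
    df$polarity <- "same"
    span <- c(min(df$start) - 4000L, max(df$stop) + 4000L)
    igh_locus(species = "SimSal", locus_id = locus_id,
              chromosome = chromosome, orientation = orientation,
              span = span, genes = df)
  }

  locus_a <- assemble(genes, "A", "chrA", "REV")
  loci <- list(A = locus_a)
  if (config$duplicate_locus)
    loci$B <- assemble(genes_b, "B", "chrB", "FWD")

  # --- positional names via the annotator ---------------------------------
  tables <- lapply(loci, function(lc) {
    layout <- order_genes(lc)
    assign_positional_names(layout)
  })
  gene_table <- do.call(rbind, tables)
  rownames(gene_table) <- NULL
  class(gene_table) <- c("igh_gene_table", "data.frame")

  # --- sequence registry keyed by allele reference ------------------------
  all_genes <- c(genes, genes_b)
  id2name <- stats::setNames(gene_table$name, gene_table$id)
  seqs <- character(); vreg <- character(); flanks <- character()
  leaders <- character()
  truth_rows <- list()
  for (g in all_genes) {
    ref <- format_allele_ref(id2name[[g$id]], 1L)
    seqs[ref] <- g$gene_nt
    vreg[ref] <- g$core
    flanks[ref] <- g$flank
    leaders[ref] <- g$leader
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      id = g$id, name = unname(id2name[[g$id]]), allele_ref = ref,
      locus_id = if (grepl("^VA", g$id)) "A" else "B",
      subgroup = g$subgroup, functionality = g$class,
      in_frame = isTRUE(g$in_frame), defect = g$defect,
      twin = isTRUE(g$twin), stringsAsFactors = FALSE)
  }
  # D and J sequences: each locus draws from its own slice of the pools
  for (lid in names(loci)) {
    li <- match(lid, names(loci)) - 1L
    g <- loci[[lid]]$genes
    d_ids <- g$id[g$group == "D"]
    j_ids <- g$id[g$group == "J"]
    for (i in which(g$group %in% c("D", "J"))) {
      ref <- format_allele_ref(id2name[[g$id[i]]], 1L)
      seqs[ref] <- if (g$group[i] == "D")
        d_pool[li * n_d_per_locus + match(g$id[i], d_ids)]
      else
        j_pool[li * n_j_per_locus + match(g$id[i], j_ids)]
    }
  }

  structure(list(config = config, loci = loci, gene_table = gene_table,
                 sequences = seqs, v_regions = vreg, flanks_3p = flanks,
                 leaders = leaders,
                 truth = do.call(rbind, truth_rows)),
            class = "igh_sim_locus")
}

.repair_stub <- function(stub) {
  codons <- substring(stub, c(1, 4), c(3, 6))
  bad <- codons %in% c(.codons_stop, "TGT", "TGC")
  codons[bad] <- "GCA"
  paste(codons, collapse = "")
}

#' Build a reference directory from a simulated locus
#'
#' @param sim an `igh_sim_locus`.
#' @param set_type directory set filter.
#' @param group gene groups to include.
#' @return an `igh_refdir` carrying sequences (V entries hold the full gene
#'   sequence including the germline CDR3 stub).
#' @export
sim_directory <- function(sim, set_type = "F_ORF_INFRAME_P",
                          group = c("V", "D", "J")) {
  build_directory(sim$gene_table, set_type = set_type, group = group,
                  sequences = sim$sequences)
}

#' Simulate a rearranged repertoire with ground truth
#'
#' Per read: draw a V, D and J allele from the directory (uniformly or by
#' `v_weights`), trim the V 3' end, both D sides and the J 5' end, insert
#' geometric-length N additions at both junction boundaries, concatenate,
#' then apply uniform per-base substitutions. With UMIs enabled, each
#' molecule is emitted `umi_dup` times under one UMI.
#'
#' @param directory an `igh_refdir` with V, D and J entries (sequences
#'   required), e.g. from [sim_directory()].
#' @param config an [sim_config()].
#' @return a list of class `igh_sim_repertoire`: `reads` (named character
#'   vector) and `truth` (data.frame: source alleles, trims, N lengths,
#'   mutation count, junction ground truth, UMI).
#' @export
simulate_repertoire <- function(directory, config) {
  stopifnot(inherits(config, "igh_sim_config"))
  set.seed(config$seed + 1L)
  e <- directory$entries
  grp <- .row_group(e$gene)
  v_e <- e[grp == "V", , drop = FALSE]
  d_e <- e[grp == "D", , drop = FALSE]
  j_e <- e[grp == "J", , drop = FALSE]
  if (nrow(v_e) == 0L || nrow(d_e) == 0L || nrow(j_e) == 0L)
    stop("directory must hold V, D and J entries", call. = FALSE)
  w <- if (is.null(config$v_weights)) rep(1, nrow(v_e)) else {
    miss <- setdiff(names(config$v_weights), v_e$allele_ref)
    if (length(miss)) stop("v_weights name unknown allele(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    ifelse(v_e$allele_ref %in% names(config$v_weights),
           config$v_weights[v_e$allele_ref], 0)
  }
  n_mol <- config$n_reads
  reads <- character(); truth <- vector("list", 0L)
  geom_p <- 1 / (config$n_mean + 1)
  for (i in seq_len(n_mol)) {
    vi <- sample(nrow(v_e), 1, prob = w)
    di <- sample(nrow(d_e), 1)
    ji <- sample(nrow(j_e), 1)
    vseq <- v_e$sequence[vi]; dseq <- d_e$sequence[di]; jseq <- j_e$sequence[ji]
    tv <- sample(config$trim_v, 1)
    td5 <- sample(config$trim_d, 1); td3 <- sample(config$trim_d, 1)
    tj <- sample(config$trim_j, 1)
    v_part <- substr(vseq, 1, nchar(vseq) - tv)
    d_part <- if (td5 + td3 >= nchar(dseq)) "" else
      substr(dseq, 1 + td5, nchar(dseq) - td3)
    j_part <- substring(jseq, 1 + tj)
    n1 <- stats::rgeom(1, geom_p); n2 <- stats::rgeom(1, geom_p)
    read <- paste0(v_part, .random_nt(n1), d_part, .random_nt(n2), j_part)
    n_mut <- 0L
    if (config$mutation_rate > 0) {
      bases <- strsplit(read, "")[[1]]
      hit <- which(stats::runif(length(bases)) < config$mutation_rate)
      for (p in hit)
        bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1)
      n_mut <- length(hit)
      read <- paste(bases, collapse = "")
    }
    umi <- if (config$umi) .random_nt(config$umi_length) else NA_character_
    reps <- if (config$umi) config$umi_dup else 1L
    for (r in seq_len(reps)) {
      rid <- sprintf("read%05d%s", i, if (reps > 1L) paste0("_", r) else "")
      reads[rid] <- read
      truth[[length(truth) + 1L]] <- data.frame(
        sequence_id = rid, v_truth = v_e$allele_ref[vi],
        d_truth = d_e$allele_ref[di], j_truth = j_e$allele_ref[ji],
        v_gene_truth = v_e$gene[vi], d_gene_truth = d_e$gene[di],
        j_gene_truth = j_e$gene[ji],
        trim_v = tv, trim_d5 = td5, trim_d3 = td3, trim_j = tj,
        n1 = n1, n2 = n2, d_retained = nchar(d_part), n_mutations = n_mut,
        umi = umi, stringsAsFactors = FALSE)
    }
  }
  structure(list(reads = reads, truth = do.call(rbind, truth)),
            class = "igh_sim_repertoire")
}

#' Write simulated reads as FASTQ
#'
#' @param reads named character vector of reads.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  set <- Biostrings::DNAStringSet(reads)
  Biostrings::writeXStringSet(
    set, path, format = "fastq",
    qualities = Biostrings::BStringSet(
      vapply(nchar(reads), function(n) strrep("I", n), "")))
  invisible(path)
}
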