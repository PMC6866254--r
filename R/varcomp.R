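#' Germline variant tallies and comparative phylogenetics
#'
#' Tallies SNPs and indels over germline V genes, classifies SNPs as silent
#' or non-silent by codon substitution, compares non-silent proportions
#' between regions (Fisher's exact test primary, chi-square with continuity
#' correction secondary), and builds UPGMA trees with column-resampling
#' bootstrap support.
#'
#' @name varcomp
NULL

#' Read a per-gene variant summary table
#'
#' Expected columns: `chromosome`, `start`, `stop`, `name`, `class`
#' (`functional`/`pseudogene`), `snp`, `ns` (non-silent SNPs; `NA` where
#' not reported), `indel`. Symbols are normalized and reversed coordinate
#' pairs flagged as opposite polarity, as for gene tables.
#'
#' @param path TSV file.
#' @return a data.frame of class `igh_variant_summary`.
#' @export
read_variant_summary <- function(path) {
  v <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  nm <- normalize_gene_names(v$name)
  v$name <- as.character(nm)
  v$polarity <- "same"
  rev_rows <- which(v$start > v$stop)
  if (length(rev_rows)) {
    tmp <- v$start[rev_rows]
    v$start[rev_rows] <- v$stop[rev_rows]
    v$stop[rev_rows] <- tmp
    v$polarity[rev_rows] <- "opposite"
  }
  class(v) <- c("igh_variant_summary", "data.frame")
  attr(v, "normalizations") <- attr(nm, "normalized")
  v
}

#' Class-level variant totals
#'
#' Sums per-gene counts by chromosome and gene class; the per-class totals
#' equal the sums of their member genes by construction.
#'
#' @param vs an `igh_variant_summary`.
#' @return data.frame: `chromosome`, `class`, `n_genes`, `snp`, `ns`,
#'   `indel` (with `ns` summed over genes reporting it).
#' @export
variant_class_totals <- function(vs) {
  key <- interaction(vs$chromosome, vs$class, sep = "\r", drop = TRUE)
  rows <- lapply(split(seq_len(nrow(vs)), key), function(idx) {
    data.frame(chromosome = vs$chromosome[idx[1]], class = vs$class[idx[1]],
               n_genes = length(idx), snp = sum(vs$snp[idx]),
               ns = if (all(is.na(vs$ns[idx]))) NA_integer_ else
                 sum(vs$ns[idx], na.rm = TRUE),
               indel = sum(vs$indel[idx]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$chromosome, out$class), , drop = FALSE]
}

#' Tally individual variants over genes
#'
#' SNP effects are computed by codon substitution in the given reading
#' frame: silent when the encoded amino acid is unchanged. Variants on
#' genes without a defined frame (pseudogenes) get effect `NA`: they count
#' in the SNP totals but never as non-silent.
#'
#' @param variants data.frame: `gene`, `position` (1-based within the
#'   V-REGION), `ref`, `alt` (SNP: single bases; differing lengths are
#'   indels).
#' @param sequences named character vector of V-REGION sequences per gene.
#' @param gene_class named character vector (`functional`/`pseudogene`) per
#'   gene; pseudogenes have no defined frame.
#' @param chromosome optional named chromosome labels per gene.
#' @return list of class `igh_variant_tally`: `per_variant` (with `kind`
#'   and `effect`), `per_gene` (snp/ns/indel counts), `per_class`
#'   (aggregated by class and chromosome).
#' @export
tally_variants <- function(variants, sequences, gene_class,
                           chromosome = NULL) {
  stopifnot(all(c("gene", "position", "ref", "alt") %in% names(variants)))
  unknown <- setdiff(variants$gene, names(gene_class))
  if (length(unknown))
    stop("variant(s) on unknown gene(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  n <- nrow(variants)
  kind <- ifelse(nchar(variants$ref) == 1L & nchar(variants$alt) == 1L,
                 "SNP", "INDEL")
  effect <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (kind[i] != "SNP") next
    g <- variants$gene[i]
    if (!identical(unname(gene_class[g]), "functional")) next
    seq <- sequences[[g]]
    if (is.null(seq) || is.na(seq)) next
    p <- variants$position[i]
    if (p < 1L || p > nchar(seq))
      stop("variant position ", p, " outside gene ", g, call. = FALSE)
    if (substr(seq, p, p) != variants$ref[i])
      stop("reference mismatch at ", g, ":", p, call. = FALSE)
    ci <- (p - 1L) %/% 3L
    codon <- substr(seq, 3L * ci + 1L, 3L * ci + 3L)
    off <- p - 3L * ci
    alt_codon <- codon
    substr(alt_codon, off, off) <- variants$alt[i]
    effect[i] <- if (identical(translate_nt(codon), translate_nt(alt_codon)))
      "SILENT" else "NON_SILENT"
  }
  pv <- cbind(variants, kind = kind, effect = effect)
  if (n == 0L) {
    empty_gene <- data.frame(gene = character(), snp = integer(),
                             ns = integer(), indel = integer(),
                             class = character(), chromosome = character(),
                             stringsAsFactors = FALSE)
    empty_class <- data.frame(class = character(), chromosome = character(),
                              snp = integer(), ns = integer(),
                              indel = integer(), stringsAsFactors = FALSE)
    return(structure(list(per_variant = pv, per_gene = empty_gene,
                          per_class = empty_class),
                     class = "igh_variant_tally"))
  }
  per_gene <- do.call(rbind, lapply(split(seq_len(n), variants$gene),
                                    function(idx) data.frame(
    gene = variants$gene[idx[1]],
    snp = sum(kind[idx] == "SNP"),
    ns = sum(effect[idx] == "NON_SILENT", na.rm = TRUE),
    indel = sum(kind[idx] == "INDEL"), stringsAsFactors = FALSE)))
  per_gene$class <- unname(gene_class[per_gene$gene])
  per_gene$chromosome <- if (is.null(chromosome)) NA_character_ else
    unname(chromosome[per_gene$gene])
  key <- interaction(per_gene$class, per_gene$chromosome, sep = "\r",
                     drop = TRUE)
  per_class <- do.call(rbind, lapply(split(seq_len(nrow(per_gene)), key),
                                     function(idx) data.frame(
    class = per_gene$class[idx[1]], chromosome = per_gene$chromosome[idx[1]],
    snp = sum(per_gene$snp[idx]), ns = sum(per_gene$ns[idx]),
    indel = sum(per_gene$indel[idx]), stringsAsFactors = FALSE)))
  rownames(per_gene) <- rownames(per_class) <- NULL
  structure(list(per_variant = pv, per_gene = per_gene,
                 per_class = per_class),
            class = "igh_variant_tally")
}

#' Compare non-silent proportions between two regions
#'
#' Builds the 2x2 table of non-silent vs silent SNPs by region and reports
#' Fisher's exact two-sided p-value (primary) and the continuity-corrected
#' chi-square statistic (secondary). The significance flag at alpha is
#' reported, never consumed downstream.
#'
#' @param x either a 2x2 matrix `rbind(c(ns_a, silent_a), c(ns_b,
#'   silent_b))`, or the `ns` count of region a (with `snp_a`, `ns_b`,
#'   `snp_b` supplied).
#' @param snp_a,ns_b,snp_b total and non-silent SNP counts when `x` is a
#'   scalar `ns_a`.
#' @param alpha significance level for the reported flag (default 0.05).
#' @return list of class `igh_ns_comparison`: `table`, `fisher_p`,
#'   `chisq_stat`, `chisq_p`, `significant`, `alpha`.
#' @export
compare_ns_proportions <- function(x, snp_a = NULL, ns_b = NULL,
                                   snp_b = NULL, alpha = 0.05) {
  tab <- if (is.matrix(x)) x else
    rbind(c(x, snp_a - x), c(ns_b, snp_b - ns_b))
  if (!all(dim(tab) == c(2L, 2L)) || any(tab < 0))
    stop("need a 2x2 table of non-negative counts", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margin: a row or column total is zero", call. = FALSE)
  dimnames(tab) <- list(region = c("a", "b"),
                        effect = c("non_silent", "silent"))
  fis <- stats::fisher.test(tab)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  structure(list(table = tab, fisher_p = fis$p.value,
                 chisq_stat = unname(chi$statistic),
                 chisq_p = chi$p.value,
                 significant = fis$p.value < alpha, alpha = alpha),
            class = "igh_ns_comparison")
}

#' @export
print.igh_ns_comparison <- function(x, ...) {
  cat("<ns-proportion comparison> Fisher p =", signif(x$fisher_p, 4),
      "| chi-square =", signif(x$chisq_stat, 4),
      "(p =", paste0(signif(x$chisq_p, 4), ");"),
      if (x$significant) "significant" else "not significant",
      "at alpha =", x$alpha, "\n")
  invisible(x)
}

#' Fraction of differing columns between aligned sequences
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences.
#' @return symmetric distance matrix (1 - column identity).
#' @export
aligned_distance <- function(alignment) {
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequences differ in length", call. = FALSE)
  mat <- do.call(rbind, strsplit(alignment, ""))
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- mean(mat[i, ] != mat[j, ])
  d
}

#' UPGMA tree with optional bootstrap support
#'
#' Agglomerative average-linkage clustering; node heights are half the
#' merged average distance, so root-to-leaf path lengths are equal
#' (ultrametric). Bootstrap resamples alignment columns with replacement,
#' recomputes the tree per replicate, and reports clade support as a
#' percentage; deterministic under the supplied seed.
#'
#' @param d symmetric non-negative distance matrix (or `dist`).
#' @param alignment optional named, aligned sequences for the bootstrap
#'   (equal lengths; the main `d` is used for the reference tree).
#' @param n_replicates bootstrap replicates (e.g. 1000).
#' @param seed seed for the resampling.
#' @return an `ape::phylo` tree; with bootstrap, `node.label` carries the
#'   support percentages and `attr(, "n_replicates")` the replicate count.
#' @export
upgma_tree <- function(d, alignment = NULL, n_replicates = 0, seed = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-10, check.attributes = FALSE)))
    stop("distance matrix must be symmetric", call. = FALSE)
  if (any(d < 0)) stop("distances must be non-negative", call. = FALSE)
  tree <- phangorn::upgma(stats::as.dist(d))
  if (!is.null(alignment) && n_replicates > 0) {
    if (!is.null(seed)) set.seed(seed)
    L <- unique(nchar(alignment))
    if (length(L) != 1L) stop("ragged alignment", call. = FALSE)
    cols <- do.call(rbind, strsplit(alignment, ""))
    boots <- vector("list", n_replicates)
    for (b in seq_len(n_replicates)) {
      idx <- sample.int(L, L, replace = TRUE)
      sub <- cols[, idx, drop = FALSE]
      n <- nrow(sub)
      db <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
        db[i, j] <- db[j, i] <- mean(sub[i, ] != sub[j, ])
      boots[[b]] <- phangorn::upgma(stats::as.dist(db))
    }
    counts <- ape::prop.clades(tree, boots, rooted = TRUE)
    counts[is.na(counts)] <- 0
    tree$node.label <- round(100 * counts / n_replicates, 1)
    attr(tree, "n_replicates") <- n_replicates
  }
  tree
}

#' Check a tree for ultrametricity
#'
#' @param tree an `ape::phylo`.
#' @param tol tolerance on root-to-leaf path-length spread.
#' @return logical.
#' @export
is_ultrametric_tree <- function(tree, tol = 1e-9) {
  ape::is.ultrametric(tree, tol = tol, option = 1)
}
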