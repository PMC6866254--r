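#' V-REGION identity and subgroup clustering
#'
#' IGHV subgroups are defined by nucleotide identity of the V-REGION: two
#' genes belong to the same subgroup when their V-REGIONs share at least 75%
#' identity. Identity here is computed on a global alignment (match +1,
#' mismatch 0, gap open -4, gap extend -1) as the fraction of identical
#' columns among aligned columns after stripping terminal-gap columns; the
#' scoring scheme is configurable but these defaults follow common
#' germline-database practice.
#'
#' @name identity
NULL

.check_nt <- function(x, what = "sequence") {
  x <- toupper(as.character(x))
  if (length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a non-empty nucleotide string", call. = FALSE)
  if (grepl("[^ACGTN]", x))
    stop(what, " contains non-nucleotide characters", call. = FALSE)
  x
}

.identity_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      letters <- c("A", "C", "G", "T", "N")
      m <- matrix(0, 5, 5, dimnames = list(letters, letters))
      diag(m) <- 1
      m["N", ] <- 0; m[, "N"] <- 0  # N never counts as a match
      cache <<- m
    }
    cache
  }
})

#' Pairwise V-REGION nucleotide identity
#'
#' Global alignment of two nucleotide sequences followed by column counting:
#' identical columns divided by aligned columns, terminal-gap columns
#' excluded. Symmetric in its arguments.
#'
#' @details
#' When several alignments share the optimal score they can differ slightly
#' in their identical-column count; to keep the statistic exactly symmetric
#' in its arguments and invariant under simultaneous reverse-complement,
#' the computation is canonicalized: the pair is evaluated in lexicographic
#' order on both strands and the larger identity is returned.
#'
#' @param a,b nucleotide strings (alphabet A/C/G/T/N).
#' @param gap_opening,gap_extension gap penalties (positive costs).
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, gap_opening = 4, gap_extension = 1) {
  a <- .check_nt(a, "a"); b <- .check_nt(b, "b")
  rc <- function(x)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  ordered <- function(x, y) if (x <= y) c(x, y) else c(y, x)
  p1 <- ordered(a, b)
  p2 <- ordered(rc(a), rc(b))
  max(.identity_one(p1[1], p1[2], gap_opening, gap_extension),
      .identity_one(p2[1], p2[2], gap_opening, gap_extension))
}

.identity_one <- function(a, b, gap_opening, gap_extension) {
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = "global", substitutionMatrix = .identity_submat(),
    gapOpening = gap_opening, gapExtension = gap_extension)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- p == "-" | s == "-"
  first <- 1L
  while (first <= length(p) && gap[first]) first <- first + 1L
  last <- length(p)
  while (last >= first && gap[last]) last <- last - 1L
  if (last < first) return(0)
  keep <- first:last
  sum(p[keep] == s[keep] & p[keep] != "-") / length(keep)
}

#' All-pairs identity matrix
#'
#' @param seqs a named character vector or `Biostrings::DNAStringSet` of
#'   V-REGION nucleotide sequences.
#' @param ... passed on to [pairwise_identity()].
#' @return a symmetric matrix of identity fractions with unit diagonal,
#'   of class `igh_identity`.
#' @export
identity_matrix <- function(seqs, ...) {
  nm <- names(seqs)
  seqs <- stats::setNames(as.character(seqs), nm)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must carry unique names", call. = FALSE)
  n <- length(seqs)
  m <- diag(1, n)
  dimnames(m) <- list(names(seqs), names(seqs))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
      m[i, j] <- m[j, i] <- pairwise_identity(seqs[[i]], seqs[[j]], ...)
  }
  class(m) <- c("igh_identity", class(m))
  m
}

.check_identity_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("identity matrix must be square", call. = FALSE)
  if (is.null(rownames(m))) stop("identity matrix must be labeled", call. = FALSE)
  if (!isTRUE(all.equal(unclass(m), t(unclass(m)), tolerance = 1e-12,
                        check.attributes = FALSE)))
    stop("identity matrix must be symmetric", call. = FALSE)
  if (any(m < 0 | m > 1)) stop("identities must lie in [0, 1]", call. = FALSE)
  invisible(m)
}

#' Cluster sequences into subgroups at an identity threshold
#'
#' Subgroups are the connected components of the graph with an edge wherever
#' pairwise identity meets the threshold (single linkage, matching the
#' subgroup notion: membership is transitive through intermediate
#' sequences). Labels are consecutive integers assigned in ascending order
#' of each component's lexicographically smallest member ID; singleton
#' subgroups are allowed.
#'
#' @param m a symmetric labeled identity matrix (see [identity_matrix()]).
#' @param threshold identity fraction defining subgroup co-membership
#'   (default 0.75).
#' @return an object of class `igh_subgroups`: list with `assignment`
#'   (named integer vector), `threshold`, and `linkage`.
#' @export
cluster_subgroups <- function(m, threshold = 0.75) {
  .check_identity_matrix(m)
  adj <- unclass(m) >= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # relabel components by their lexicographically smallest member
  smallest <- tapply(names(comp), comp, function(x) sort(x)[1])
  relabel <- match(comp, as.integer(names(sort(smallest))))
  assignment <- stats::setNames(relabel, rownames(m))
  structure(list(assignment = assignment, threshold = threshold,
                 linkage = "single"),
            class = "igh_subgroups")
}

#' @export
print.igh_subgroups <- function(x, ...) {
  cat("<igh_subgroups> ", max(x$assignment), " subgroup(s) at threshold ",
      x$threshold, " (", x$linkage, " linkage)\n", sep = "")
  invisible(x)
}

#' Assign a sequence to an existing reference subgroup
#'
#' Compares a query V-REGION against every allele of a reference directory
#' and returns the subgroup of the highest-identity allele provided that
#' identity meets the threshold; otherwise `"NEW"` (a new subgroup would
#' have to be defined). Ties on identity across subgroups are broken toward
#' the lower subgroup number and flagged.
#'
#' @param seq query nucleotide sequence.
#' @param directory a reference directory with sequences
#'   (see [build_directory()]).
#' @param threshold identity threshold (default 0.75).
#' @return a list: `subgroup` (integer or the string "NEW"), `best_identity`,
#'   `best_allele`, `tie` (logical, identical best identity in more than one
#'   subgroup).
#' @export
assign_to_reference_subgroups <- function(seq, directory, threshold = 0.75) {
  entries <- directory$entries
  entries <- entries[!is.na(entries$sequence) & nzchar(entries$sequence), ]
  if (nrow(entries) == 0L)
    stop("reference directory holds no sequences", call. = FALSE)
  ids <- vapply(entries$sequence, function(s) pairwise_identity(seq, s),
                numeric(1))
  best <- max(ids)
  if (best < threshold)
    return(list(subgroup = "NEW", best_identity = best,
                best_allele = NA_character_, tie = FALSE))
  at_best <- which(ids >= best - 1e-12)
  subs <- sort(unique(entries$subgroup[at_best]))
  tie <- length(subs) > 1L
  if (tie)
    message("subgroup tie at identity ", signif(best, 4), " between subgroups ",
            paste(subs, collapse = ", "), "; keeping ", subs[1])
  pick <- at_best[entries$subgroup[at_best] == subs[1]][1]
  list(subgroup = subs[1], best_identity = best,
       best_allele = entries$allele_ref[pick], tie = tie)
}
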