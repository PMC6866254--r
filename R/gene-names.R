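#' @title Salmonid IGH gene-name grammar
#'
#' @description
#' Structured representation of salmonid IGH germline gene symbols and the
#' bidirectional grammar between symbol strings and their components.
#'
#' A salmonid IGH gene symbol is built from:
#' \itemize{
#'   \item the group letter: \code{V}, \code{D} (diversity), \code{J}, or a
#'     constant-gene isotype letter (\code{M}, \code{D} for Delta, \code{T});
#'   \item for V genes, the subgroup number (genes sharing >= 75\% V-REGION
#'     nucleotide identity);
#'   \item a trailing \code{D} after the numeric body marking locus B of the
#'     duplicated (tetraploid) locus pair;
#'   \item a hyphenated number giving the position along the locus (V genes
#'     and dispersed diversity genes), or an unhyphenated cluster index for
#'     D/J genes inside a D-J-C cluster;
#'   \item an optional \code{T<m>} infix on D/J genes naming the IGHT (tau)
#'     constant gene whose cluster they belong to;
#'   \item an \code{S<k>} suffix for provisional names of genes not yet
#'     localized on an assembly.
#' }
#' \code{"IGHD"} with no digits is the Delta constant gene and \code{"IGHDD"}
#' its locus-B homolog; \code{"IGHD"} followed by a digit or hyphen is a
#' diversity gene.
#'
#' @name gene-names
NULL

.igh_groups <- c("V", "D", "J", "C")

#' Construct a gene-name object
#'
#' Low-level constructor; most users go through [parse_gene_name()].
#'
#' @param group one of `"V"`, `"D"`, `"J"`, `"C"`.
#' @param isotype constant-gene isotype (`"M"`, `"Delta"`, `"T"`); `NA`
#'   except for C genes.
#' @param subgroup subgroup number (V genes) or tau series number (IGHT
#'   constant genes); `NA` otherwise.
#' @param duplicated `TRUE` for locus-B genes (rendered with the `D` suffix).
#' @param position hyphenated locus position (V genes, dispersed D genes).
#' @param c_tag tau-cluster tag such as `"T2"` for D/J genes, else `NA`.
#' @param cluster_index unhyphenated within-cluster number of D/J genes.
#' @param provisional `TRUE` for provisional `S` names.
#' @param s_number numeric part of a provisional `S` name.
#' @return an object of class `igh_gene_name`.
#' @export
gene_name <- function(group, isotype = NA_character_, subgroup = NA_integer_,
                      duplicated = FALSE, position = NA_integer_,
                      c_tag = NA_character_, cluster_index = NA_integer_,
                      provisional = FALSE, s_number = NA_integer_) {
  gn <- structure(
    list(group = group, isotype = isotype,
         subgroup = if (is.na(subgroup)) NA_integer_ else as.integer(subgroup),
         duplicated = isTRUE(duplicated),
         position = if (is.na(position)) NA_integer_ else as.integer(position),
         c_tag = c_tag,
         cluster_index = if (is.na(cluster_index)) NA_integer_ else as.integer(cluster_index),
         provisional = isTRUE(provisional),
         s_number = if (is.na(s_number)) NA_integer_ else as.integer(s_number)),
    class = "igh_gene_name")
  validate_gene_name(gn)
  gn
}

#' Validate gene-name invariants
#'
#' Checks the structural invariants of a gene-name object: V genes carry a
#' position (or a provisional S number), D and J genes carry exactly one of
#' position/cluster index (J genes never a position), C genes neither; an
#' isotype is present if and only if the group is C; a tau-cluster tag only
#' appears on D/J genes.
#'
#' @param gn an `igh_gene_name`.
#' @return `gn`, invisibly; errors on violation.
#' @export
validate_gene_name <- function(gn) {
  stopifnot(inherits(gn, "igh_gene_name"))
  fail <- function(msg) stop("invalid gene name: ", msg, call. = FALSE)
  if (!gn$group %in% .igh_groups) fail(paste0("unknown group '", gn$group, "'"))
  if ((gn$group == "C") != !is.na(gn$isotype))
    fail("isotype must be set exactly when group is C")
  if (!is.na(gn$c_tag) && !gn$group %in% c("D", "J"))
    fail("c_tag only applies to D and J genes")
  has_pos <- !is.na(gn$position)
  has_idx <- !is.na(gn$cluster_index)
  if (gn$group == "V") {
    if (gn$provisional) {
      if (is.na(gn$s_number) || has_pos) fail("provisional V gene needs S number, no position")
    } else if (!has_pos || has_idx) fail("V gene needs a position, never a cluster index")
    if (is.na(gn$subgroup)) fail("V gene needs a subgroup")
  }
  if (gn$group == "D" && !is.na(gn$isotype)) fail("diversity gene cannot carry an isotype")
  if (gn$group %in% c("D", "J")) {
    if (has_pos == has_idx) fail("exactly one of position/cluster index for D and J genes")
    if (gn$group == "J" && has_pos) fail("J genes are never hyphen-positioned")
  }
  if (gn$group == "C") {
    if (has_pos || has_idx) fail("C genes carry neither position nor cluster index")
    if (gn$isotype == "T" && is.na(gn$subgroup)) fail("IGHT constant gene needs a series number")
    if (gn$isotype %in% c("M", "Delta") && !is.na(gn$subgroup))
      fail("IGHM/IGHD constant genes carry no subgroup number")
  }
  invisible(gn)
}

#' Parse a salmonid IGH gene symbol
#'
#' @param s a single uppercase gene symbol, e.g. `"IGHV6D-76"`, `"IGHD1T2D"`,
#'   `"IGHDD"`, `"IGHD-5"`, `"IGHT1D"`, `"IGHJ2T4"`, `"IGHV1S3"`.
#' @return an `igh_gene_name`.
#' @examples
#' parse_gene_name("IGHV6D-76")   # V subgroup 6, locus B, position 76
#' parse_gene_name("IGHDD")       # the locus-B Delta constant gene
#' parse_gene_name("IGHD1T2D")    # diversity gene 1 of the IGHT2D cluster
#' @export
parse_gene_name <- function(s) {
  if (length(s) != 1L || !is.character(s) || is.na(s) || !nzchar(s))
    stop("gene name must be a single non-empty string", call. = FALSE)
  if (grepl("[a-z]", s))
    stop("gene name must be uppercase: '", s, "'", call. = FALSE)
  if (!startsWith(s, "IGH"))
    stop("unparsable gene name '", s, "': expected 'IGH' prefix, got '",
         substr(s, 1, 3), "'", call. = FALSE)
  rest <- substring(s, 4)
  if (!nzchar(rest))
    stop("unparsable gene name '", s, "': missing group letter", call. = FALSE)
  first <- substr(rest, 1, 1)
  num <- "([1-9][0-9]*)"
  if (first == "M") {
    if (rest == "M")  return(gene_name("C", isotype = "M"))
    if (rest == "MD") return(gene_name("C", isotype = "M", duplicated = TRUE))
    stop("unparsable gene name '", s, "': bad token after 'IGHM'", call. = FALSE)
  }
  if (first == "T") {
    m <- regmatches(rest, regexec(paste0("^T", num, "(D?)$"), rest))[[1]]
    if (length(m))
      return(gene_name("C", isotype = "T", subgroup = as.integer(m[2]),
                       duplicated = m[3] == "D"))
    stop("unparsable gene name '", s, "': bad IGHT series token '", rest, "'",
         call. = FALSE)
  }
  if (first == "V") {
    m <- regmatches(rest, regexec(paste0("^V", num, "(D?)-", num, "$"), rest))[[1]]
    if (length(m))
      return(gene_name("V", subgroup = as.integer(m[2]), duplicated = m[3] == "D",
                       position = as.integer(m[4])))
    m <- regmatches(rest, regexec(paste0("^V", num, "(D?)S", num, "$"), rest))[[1]]
    if (length(m))
      return(gene_name("V", subgroup = as.integer(m[2]), duplicated = m[3] == "D",
                       provisional = TRUE, s_number = as.integer(m[4])))
    stop("unparsable gene name '", s, "': bad V-gene token '", rest, "'",
         call. = FALSE)
  }
  if (first == "J") {
    m <- regmatches(rest, regexec(paste0("^J", num, "(T", num, ")?(D?)$"), rest))[[1]]
    if (length(m))
      return(gene_name("J", cluster_index = as.integer(m[2]),
                       c_tag = if (nzchar(m[3])) m[3] else NA_character_,
                       duplicated = m[5] == "D"))
    stop("unparsable gene name '", s, "': bad J-gene token '", rest, "'",
         call. = FALSE)
  }
  if (first == "D") {
    # bare IGHD / IGHDD are the Delta constant genes; a following digit or
    # hyphen switches the interpretation to a diversity gene
    if (rest == "D")  return(gene_name("C", isotype = "Delta"))
    if (rest == "DD") return(gene_name("C", isotype = "Delta", duplicated = TRUE))
    m <- regmatches(rest, regexec(paste0("^D-", num, "(D?)$"), rest))[[1]]
    if (length(m))
      return(gene_name("D", position = as.integer(m[2]), duplicated = m[3] == "D"))
    m <- regmatches(rest, regexec(paste0("^D", num, "(T", num, ")?(D?)$"), rest))[[1]]
    if (length(m))
      return(gene_name("D", cluster_index = as.integer(m[2]),
                       c_tag = if (nzchar(m[3])) m[3] else NA_character_,
                       duplicated = m[5] == "D"))
    stop("unparsable gene name '", s, "': bad D-gene token '", rest, "'",
         call. = FALSE)
  }
  stop("unparsable gene name '", s, "': invalid group letter '", first, "'",
       call. = FALSE)
}

#' Render a gene-name object as its canonical symbol
#'
#' Inverse of [parse_gene_name()]: `format_gene_name(parse_gene_name(s))`
#' equals `s` for every valid symbol.
#'
#' @param gn an `igh_gene_name`.
#' @return a single string.
#' @export
format_gene_name <- function(gn) {
  validate_gene_name(gn)
  dup <- if (gn$duplicated) "D" else ""
  if (gn$group == "C") {
    body <- switch(gn$isotype,
                   M = "M",
                   Delta = "D",
                   T = paste0("T", gn$subgroup))
    return(paste0("IGH", body, dup))
  }
  if (gn$group == "V") {
    tail <- if (gn$provisional) paste0("S", gn$s_number) else paste0("-", gn$position)
    return(paste0("IGHV", gn$subgroup, dup, tail))
  }
  tag <- if (is.na(gn$c_tag)) "" else gn$c_tag
  if (gn$group == "D" && !is.na(gn$position))
    return(paste0("IGHD-", gn$position, dup))
  paste0("IGH", gn$group, gn$cluster_index, tag, dup)
}

#' @export
format.igh_gene_name <- function(x, ...) format_gene_name(x)

#' @export
print.igh_gene_name <- function(x, ...) {
  cat("<igh_gene_name> ", format_gene_name(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.igh_gene_name` <- function(e1, e2) {
  identical(format_gene_name(e1), format_gene_name(e2))
}

#' Render an allele reference
#'
#' Allele references are `GENE*NN` with a zero-padded two-digit allele
#' number, e.g. `"IGHV1-64*01"`.
#'
#' @param gene an `igh_gene_name` or a gene symbol string.
#' @param allele_number positive integer.
#' @return a string.
#' @export
format_allele_ref <- function(gene, allele_number) {
  if (inherits(gene, "igh_gene_name")) gene <- format_gene_name(gene)
  allele_number <- as.integer(allele_number)
  if (any(is.na(allele_number)) || any(allele_number < 1L))
    stop("allele_number must be >= 1", call. = FALSE)
  sprintf("%s*%02d", gene, allele_number)
}

#' Split an allele reference into gene symbol and allele number
#'
#' @param ref strings such as `"IGHV1D-25*01"`.
#' @return a data.frame with columns `gene` and `allele_number`; the gene
#'   symbols are validated through the grammar.
#' @export
parse_allele_ref <- function(ref) {
  parts <- regmatches(ref, regexec("^(.+)\\*([0-9]{2,})$", ref))
  bad <- vapply(parts, length, 1L) == 0L
  if (any(bad))
    stop("malformed allele reference '", ref[bad][1], "'", call. = FALSE)
  gene <- vapply(parts, `[`, "", 2L)
  for (g in unique(gene)) parse_gene_name(g)
  data.frame(gene = gene,
             allele_number = as.integer(vapply(parts, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}
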