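#' Reference directory sets
#'
#' A reference directory is the filtered set of germline alleles used as the
#' alignment target for repertoire annotation. Two set types exist:
#' `"F_ORF"` (functional and ORF alleles) and `"F_ORF_INFRAME_P"` (adding
#' pseudogene alleles whose V-REGION frame is open). Out-of-frame
#' pseudogenes are always excluded. Filtering is per allele: a functional
#' allele of a gene enters the set even when another allele of the same gene
#' is a pseudogene.
#'
#' @name refdir
NULL

.functionality_rank <- c(F = 1L, ORF = 2L, P = 3L)

.row_group <- function(names) {
  vapply(names, function(n) parse_gene_name(n)$group, "", USE.NAMES = FALSE)
}

#' Build a reference directory from a gene table
#'
#' @param table a validated gene table ([read_gene_table()]); the table is
#'   re-validated and rejected if any row fails.
#' @param set_type `"F_ORF"` or `"F_ORF_INFRAME_P"`.
#' @param species optional species filter (matched against the `species`
#'   column).
#' @param group gene group to include (default `"V"`).
#' @param one_allele_per_gene keep a single allele per gene: the best
#'   functionality (F before ORF before P), ties broken toward the lowest
#'   allele number. This is the selection used for cross-species tree
#'   building.
#' @param sequences optional named character vector of allele sequences,
#'   keyed by allele reference (`GENE*NN`).
#' @return an object of class `igh_refdir`: list with `spec` (the set
#'   specification) and `entries` (data.frame: `allele_ref`, `gene`,
#'   `allele_number`, `subgroup`, `functionality`, `in_frame`, `locus_id`,
#'   `species`, `sequence`).
#' @export
build_directory <- function(table, set_type = c("F_ORF_INFRAME_P", "F_ORF"),
                            species = NULL, group = "V",
                            one_allele_per_gene = FALSE, sequences = NULL) {
  set_type <- match.arg(set_type)
  report <- validate_gene_table(table)
  if (!attr(report, "accepted"))
    stop("gene table failed validation (", nrow(report), " failure(s)); ",
         "first: row ", report$row[1], " ", report$field[1], ": ",
         report$message[1], call. = FALSE)
  tbl <- as.data.frame(table)
  if (!is.null(species)) tbl <- tbl[tbl$species %in% species, , drop = FALSE]
  if (nrow(tbl)) tbl <- tbl[.row_group(tbl$name) %in% group, , drop = FALSE]
  fun <- trimws(tbl$functionality)
  keep <- fun %in% c("F", "ORF") |
    (set_type == "F_ORF_INFRAME_P" & fun == "P" & tbl$in_frame)
  tbl <- tbl[keep, , drop = FALSE]
  fun <- trimws(tbl$functionality)
  allele_no <- as.integer(tbl$allele)
  entries <- data.frame(
    allele_ref = if (nrow(tbl)) format_allele_ref(tbl$name, allele_no) else character(),
    gene = tbl$name,
    allele_number = allele_no,
    subgroup = tbl$subgroup,
    functionality = fun,
    in_frame = tbl$in_frame,
    locus_id = tbl$locus_id,
    species = tbl$species,
    sequence = rep(NA_character_, nrow(tbl)),
    stringsAsFactors = FALSE)
  if (anyDuplicated(entries$allele_ref))
    stop("duplicate allele references in source table: ",
         entries$allele_ref[duplicated(entries$allele_ref)][1], call. = FALSE)
  if (!is.null(sequences)) {
    idx <- match(entries$allele_ref, names(sequences))
    entries$sequence <- ifelse(is.na(idx), NA_character_,
                               toupper(unname(sequences[idx])))
  }
  if (one_allele_per_gene && nrow(entries)) {
    ord <- order(entries$gene, .functionality_rank[entries$functionality],
                 entries$allele_number)
    entries <- entries[ord, , drop = FALSE]
    entries <- entries[!duplicated(entries$gene), , drop = FALSE]
  }
  rownames(entries) <- NULL
  structure(list(
    spec = list(set_type = set_type, species = species, group = group,
                one_allele_per_gene = one_allele_per_gene),
    entries = entries,
    release = format(Sys.Date(), "%Y%m%d")),
    class = "igh_refdir")
}

#' @export
print.igh_refdir <- function(x, ...) {
  cat("<igh_refdir> ", nrow(x$entries), " allele(s), set ",
      x$spec$set_type, ", group ", paste(x$spec$group, collapse = "/"),
      "\n", sep = "")
  print(table(x$entries$functionality))
  invisible(x)
}

.region_label <- function(group) {
  paste0(c(V = "V", D = "D", J = "J", C = "C")[group], "-REGION")
}

#' Write a reference directory to FASTA
#'
#' Headers use a reduced five-field pipe-delimited dialect:
#' `alleleref|species|functionality|locus_id|region`.
#'
#' @param directory an `igh_refdir` whose entries carry sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_directory_fasta <- function(directory, path) {
  e <- directory$entries
  if (any(is.na(e$sequence)))
    stop("directory entries without sequences cannot be serialized",
         call. = FALSE)
  grp <- .row_group(e$gene)
  headers <- paste(e$allele_ref,
                   ifelse(is.na(e$species) | e$species == "", "NA", e$species),
                   e$functionality,
                   ifelse(is.na(e$locus_id) | e$locus_id == "", "NA", e$locus_id),
                   .region_label(grp), sep = "|")
  set <- Biostrings::DNAStringSet(e$sequence)
  names(set) <- headers
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a reference directory from FASTA
#'
#' Inverse of [write_directory_fasta()]; `read(write(x))` restores the
#' directory entries.
#'
#' @param path FASTA file with five-field pipe-delimited headers.
#' @param set_type set label to attach (filtering already happened when the
#'   file was written).
#' @return an `igh_refdir`.
#' @export
read_directory_fasta <- function(path, set_type = "F_ORF_INFRAME_P") {
  set <- Biostrings::readDNAStringSet(path)
  fields <- strsplit(names(set), "|", fixed = TRUE)
  check_field <- function(f, i, ok) {
    val <- if (length(f) >= i) f[[i]] else ""
    if (!ok(val))
      stop("malformed directory FASTA header '",
           paste(f, collapse = "|"), "': field ", i, call. = FALSE)
    val
  }
  rows <- lapply(fields, function(f) {
    ref <- check_field(f, 1L, function(v) grepl("\\*[0-9]{2,}$", v))
    sp <- check_field(f, 2L, nzchar)
    fun <- check_field(f, 3L, function(v) v %in% c("F", "ORF", "P"))
    loc <- check_field(f, 4L, nzchar)
    reg <- check_field(f, 5L, function(v) grepl("-REGION$", v))
    pr <- parse_allele_ref(ref)
    data.frame(allele_ref = ref, gene = pr$gene,
               allele_number = pr$allele_number,
               subgroup = parse_gene_name(pr$gene)$subgroup,
               functionality = fun, in_frame = fun == "P",
               locus_id = loc, species = sp, stringsAsFactors = FALSE)
  })
  entries <- do.call(rbind, rows)
  entries$sequence <- as.character(set)
  rownames(entries) <- NULL
  structure(list(
    spec = list(set_type = set_type, species = unique(entries$species),
                group = unique(.row_group(entries$gene)),
                one_allele_per_gene = FALSE),
    entries = entries,
    release = format(Sys.Date(), "%Y%m%d")),
    class = "igh_refdir")
}

#' Summarize a gene table
#'
#' Contingency counts of genes (or alleles) by functionality across grouping
#' keys, in the layout of a per-subgroup, per-locus gene table. In gene
#' mode, a gene whose alleles differ in functionality is counted once under
#' its best functionality (F before ORF before P); the mixed genes are also
#' reported separately as dual counts (the "(+1)" presentation).
#'
#' @param table a gene table.
#' @param group_by keys among `"subgroup"`, `"locus"`, `"functionality"`.
#' @param unit `"gene"` (default) or `"allele"`.
#' @param group gene group to summarize (default `"V"`).
#' @return a data.frame with the grouping keys and columns `F`, `ORF`, `P`,
#'   `unstated`, `Total` (unless `functionality` is itself a key, in which
#'   case a long count column is returned). Attributes: `grand_total` and,
#'   in gene mode, `dual` — a data.frame of mixed-functionality genes and
#'   the cells they additionally belong to.
#' @export
summarize_gene_table <- function(table, group_by = c("subgroup", "locus"),
                                 unit = c("gene", "allele"), group = "V") {
  unit <- match.arg(unit)
  known <- c("subgroup", "locus", "functionality")
  bad <- setdiff(group_by, known)
  if (length(bad))
    stop("unknown group_by key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  tbl <- as.data.frame(table)
  tbl <- tbl[.row_group(tbl$name) %in% group, , drop = FALSE]
  tbl$functionality <- trimws(tbl$functionality)
  tbl$functionality[tbl$functionality == "" | is.na(tbl$functionality)] <- "unstated"
  dual <- NULL
  if (unit == "gene") {
    funs_by_gene <- split(tbl$functionality, tbl$name)
    mixed <- names(funs_by_gene)[vapply(funs_by_gene, function(f)
      length(unique(f)) > 1L, TRUE)]
    if (length(mixed)) {
      dual <- do.call(rbind, lapply(mixed, function(g) {
        f <- sort(unique(funs_by_gene[[g]]))
        data.frame(gene = g, functionalities = paste(f, collapse = "/"),
                   stringsAsFactors = FALSE)
      }))
    }
    rank <- .functionality_rank[tbl$functionality]
    rank[is.na(rank)] <- 4L
    ord <- order(tbl$name, rank)
    tbl <- tbl[ord, , drop = FALSE]
    tbl <- tbl[!duplicated(tbl$name), , drop = FALSE]
  }
  key_cols <- list()
  if ("subgroup" %in% group_by) key_cols$subgroup <- tbl$subgroup
  if ("locus" %in% group_by) key_cols$locus_id <- tbl$locus_id
  if ("functionality" %in% group_by) {
    key_cols$functionality <- tbl$functionality
    counts <- as.data.frame(table(key_cols), stringsAsFactors = FALSE)
    names(counts)[ncol(counts)] <- "n"
    attr(counts, "grand_total") <- sum(counts$n)
    attr(counts, "dual") <- dual
    return(counts)
  }
  fun <- factor(tbl$functionality, levels = c("F", "ORF", "P", "unstated"))
  if (!length(key_cols)) key_cols$all <- rep("all", nrow(tbl))
  tab <- table(do.call(interaction, c(key_cols, list(drop = TRUE, sep = "\r"))),
               fun)
  keys <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  out <- data.frame(keys, stringsAsFactors = FALSE)
  names(out) <- names(key_cols)
  if ("subgroup" %in% names(out)) out$subgroup <- as.integer(out$subgroup)
  out <- cbind(out, as.data.frame.matrix(unclass(tab)))
  out$Total <- rowSums(unclass(tab))
  out <- out[order(out[[1]]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "grand_total") <- sum(out$Total)
  attr(out, "dual") <- dual
  out
}

#' Register a new allele or gene in a reference directory
#'
#' Implements the update rules for directory growth. A sequence identical to
#' an existing allele is a no-op; a sequence differing from all alleles of a
#' named gene receives the next allele number (`*02`, `*03`, ... in
#' registration order, never reused); a sequence without a gene assignment
#' is placed by [assign_to_reference_subgroups()], and when it matches no
#' subgroup at the threshold it founds a provisional `S`-named gene in a new
#' subgroup. Every decision is appended to the directory's audit log.
#'
#' @param directory an `igh_refdir` with sequences.
#' @param seq nucleotide sequence of the candidate allele.
#' @param gene optional gene symbol the allele belongs to.
#' @param species,locus_id metadata for a newly created gene.
#' @param threshold subgroup-membership threshold (default 0.75).
#' @return the updated directory; `attr(, "audit")` holds the decision log.
#' @export
register_allele <- function(directory, seq, gene = NULL,
                            species = NA_character_, locus_id = NA_character_,
                            threshold = 0.75) {
  seq <- .check_nt(seq, "seq")
  e <- directory$entries
  audit <- attr(directory, "audit") %||% list()
  log <- function(action, detail) {
    audit[[length(audit) + 1L]] <<- list(action = action, detail = detail)
  }
  hit <- which(!is.na(e$sequence) & e$sequence == seq)
  if (length(hit)) {
    log("noop", paste0("sequence identical to ", e$allele_ref[hit[1]]))
    attr(directory, "audit") <- audit
    return(directory)
  }
  fun <- classify_functionality(seq)
  add_entry <- function(gene_name, allele_number, subgroup, sp, loc) {
    data.frame(allele_ref = format_allele_ref(gene_name, allele_number),
               gene = gene_name, allele_number = allele_number,
               subgroup = subgroup, functionality = fun$value,
               in_frame = isTRUE(fun$in_frame), locus_id = loc, species = sp,
               sequence = seq, stringsAsFactors = FALSE)
  }
  if (!is.null(gene)) {
    gn <- parse_gene_name(gene)
    existing <- e[e$gene == gene, , drop = FALSE]
    if (nrow(existing) == 0L)
      stop("gene '", gene, "' not present in directory; omit `gene` to ",
           "register a new gene", call. = FALSE)
    next_no <- max(existing$allele_number) + 1L
    new <- add_entry(gene, next_no, gn$subgroup,
                     existing$species[1], existing$locus_id[1])
    log("new_allele", new$allele_ref)
  } else {
    placed <- assign_to_reference_subgroups(seq, directory, threshold)
    if (identical(placed$subgroup, "NEW")) {
      sub <- max(e$subgroup, na.rm = TRUE) + 1L
      s_no <- 1L
      log("new_subgroup", paste0("best identity ", signif(placed$best_identity, 4),
                                 " < ", threshold, "; founding subgroup ", sub))
    } else {
      sub <- placed$subgroup
      prov <- vapply(e$gene, function(g) {
        gn <- parse_gene_name(g)
        isTRUE(gn$provisional) && identical(gn$subgroup, as.integer(sub))
      }, TRUE)
      s_no <- if (any(prov))
        max(vapply(e$gene[prov], function(g) parse_gene_name(g)$s_number, 1L)) + 1L
      else 1L
    }
    gene_name_str <- format_gene_name(
      gene_name("V", subgroup = sub, provisional = TRUE, s_number = s_no))
    new <- add_entry(gene_name_str, 1L, as.integer(sub), species, locus_id)
    log("new_provisional_gene", new$allele_ref)
  }
  directory$entries <- rbind(e, new)
  rownames(directory$entries) <- NULL
  attr(directory, "audit") <- audit
  directory
}
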