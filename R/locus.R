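#' Locus models and positional nomenclature
#'
#' A locus model holds the located genes of one IGH locus (A or B) together
#' with its orientation. Annotation proceeds in three steps: sort genes into
#' biological 5'-to-3' order ([order_genes()]), associate every D and J gene
#' with a constant-gene cluster or flag it as dispersed
#' ([associate_dj_to_c()]), then assign positional names
#' ([assign_positional_names()]).
#'
#' Numbering convention: V position 1 is the V gene closest to the
#' mu (IGHM) D-J-C cluster, positions increase 3' to 5' in a single series
#' per locus shared across subgroups; V genes lying between two clusters
#' take the smallest positions. Dispersed diversity genes are hyphen-
#' numbered in the same direction. D/J genes inside a cluster are numbered
#' 1..k in 5'-to-3' order and carry the cluster's tau tag (clusters of the
#' mu/delta genes are untagged; the delta constant gene shares the mu
#' cluster and has no D-J set of its own).
#'
#' @name locus
NULL

#' Construct a locus model
#'
#' @param species species label (e.g. `"Salsal"`).
#' @param locus_id `"A"` or `"B"`.
#' @param chromosome chromosome label.
#' @param orientation `"FWD"` or `"REV"` (locus reading direction relative
#'   to the chromosome).
#' @param span two-element integer vector, 1-based inclusive.
#' @param genes data.frame with one row per gene: columns `id` (unique),
#'   `group` (`V`/`D`/`J`/`C`), `start`, `stop`, optional `polarity`,
#'   `subgroup` (V genes), `isotype` + `tau_series` (C genes),
#'   `functionality`, `c_override` (gene id of a C gene forcing the cluster
#'   association).
#' @return an object of class `igh_locus`.
#' @export
igh_locus <- function(species, locus_id, chromosome, orientation, span, genes) {
  orientation <- match.arg(orientation, c("FWD", "REV"))
  locus_id <- match.arg(locus_id, c("A", "B"))
  stopifnot(is.data.frame(genes),
            all(c("id", "group", "start", "stop") %in% names(genes)))
  if (anyDuplicated(genes$id)) stop("gene ids must be unique", call. = FALSE)
  if (!"polarity" %in% names(genes)) genes$polarity <- "same"
  if (!"c_override" %in% names(genes)) genes$c_override <- NA_character_
  structure(list(species = species, locus_id = locus_id,
                 chromosome = chromosome, orientation = orientation,
                 span = as.integer(span), genes = genes),
            class = "igh_locus")
}

#' @export
print.igh_locus <- function(x, ...) {
  cat("<igh_locus> ", x$species, " locus ", x$locus_id, " (", x$chromosome,
      ", ", x$orientation, "), ", nrow(x$genes), " genes in ",
      x$span[1], "-", x$span[2], "\n", sep = "")
  invisible(x)
}

#' Sort locus genes into biological 5'-to-3' order
#'
#' Ascending genomic coordinate for FWD loci, descending for REV loci;
#' stable tie-break by start coordinate then gene id.
#'
#' @param locus an `igh_locus`.
#' @return an `igh_locus_layout`: the locus plus `order` (gene ids 5'->3')
#'   and the reordered gene data.frame.
#' @export
order_genes <- function(locus) {
  g <- locus$genes
  outside <- g$start < locus$span[1] | g$stop > locus$span[2]
  if (any(outside))
    stop("gene(s) outside locus span: ",
         paste(g$id[outside], collapse = ", "), call. = FALSE)
  mid <- (g$start + g$stop) / 2
  ord <- if (locus$orientation == "FWD")
    order(mid, g$start, g$id) else order(-mid, -g$start, g$id)
  g <- g[ord, , drop = FALSE]
  rownames(g) <- NULL
  structure(list(locus = locus, order = g$id, genes = g),
            class = "igh_locus_layout")
}

#' @export
print.igh_locus_layout <- function(x, ...) {
  # compact text locus map, one track line per gene in 5'->3' order
  cat("<igh_locus_layout> ", x$locus$species, " locus ", x$locus$locus_id,
      " (", x$locus$orientation, ") 5'->3':\n", sep = "")
  lab <- ifelse(!is.na(x$genes$group) & x$genes$group == "C" &
                  "isotype" %in% names(x$genes),
                paste0("C[", x$genes$isotype, "]"), x$genes$group)
  cat(" ", paste(paste0(lab, ":", x$genes$id), collapse = " - "), "\n")
  invisible(x)
}

#' Associate D and J genes with constant-gene clusters
#'
#' Each D/J gene is associated with the nearest C gene downstream of it in
#' biological order, provided no V gene lies between them. A D gene with an
#' intervening V gene is `DISPERSED` (it sits among the V genes); a J gene
#' can never be dispersed. D/J genes whose cluster constant gene is an IGHT
#' (tau) gene carry that gene's tau tag; mu/delta clusters are untagged. A
#' per-gene `c_override` column forces the association (used for printed
#' layouts where a cluster's D genes sit downstream of their C gene).
#'
#' @param layout an `igh_locus_layout`.
#' @return an `igh_cluster_assoc`: data.frame (`id`, `group`, `assoc_c`,
#'   `tag`) plus an attribute `members` listing each C gene's ordered D/J
#'   members.
#' @export
associate_dj_to_c <- function(layout) {
  g <- layout$genes
  if (!any(g$group == "C"))
    stop("layout contains no constant gene", call. = FALSE)
  n <- nrow(g)
  tag_of <- function(ci) {
    if (!"isotype" %in% names(g)) return(NA_character_)
    iso <- g$isotype[ci]
    if (identical(iso, "T")) paste0("T", g$tau_series[ci]) else NA_character_
  }
  res <- list()
  for (i in which(g$group %in% c("D", "J"))) {
    if (!is.na(g$c_override[i])) {
      ci <- match(g$c_override[i], g$id)
      if (is.na(ci) || g$group[ci] != "C")
        stop("c_override of ", g$id[i], " is not a C gene", call. = FALSE)
      res[[length(res) + 1L]] <- data.frame(
        id = g$id[i], group = g$group[i], assoc_c = g$id[ci], tag = tag_of(ci),
        stringsAsFactors = FALSE)
      next
    }
    assoc <- NA_character_
    blocked <- FALSE
    j <- i + 1L
    while (j <= n) {
      if (g$group[j] == "V") { blocked <- TRUE; break }
      if (g$group[j] == "C") { assoc <- g$id[j]; break }
      j <- j + 1L
    }
    if (blocked || is.na(assoc)) {
      if (g$group[i] == "J")
        stop("J gene ", g$id[i], " has no associated constant gene ",
             "(J genes are never dispersed)", call. = FALSE)
      res[[length(res) + 1L]] <- data.frame(
        id = g$id[i], group = "D", assoc_c = "DISPERSED", tag = NA_character_,
        stringsAsFactors = FALSE)
    } else {
      ci <- match(assoc, g$id)
      res[[length(res) + 1L]] <- data.frame(
        id = g$id[i], group = g$group[i], assoc_c = assoc, tag = tag_of(ci),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(id = character(), group = character(), assoc_c = character(),
               tag = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  members <- split(out$id[out$assoc_c != "DISPERSED"],
                   out$assoc_c[out$assoc_c != "DISPERSED"])
  # preserve 5'->3' member order within each cluster
  members <- lapply(members, function(ids) ids[order(match(ids, g$id))])
  structure(out, members = members, class = c("igh_cluster_assoc", "data.frame"))
}

#' Assign positional names along a locus
#'
#' @param layout an `igh_locus_layout`.
#' @param subgroups optional `igh_subgroups` (or named integer vector keyed
#'   by gene id) giving each V gene's subgroup; defaults to the layout's
#'   `subgroup` column.
#' @param assoc the cluster association from [associate_dj_to_c()]
#'   (computed if missing).
#' @return an `igh_gene_table` data.frame with assigned `name` per gene
#'   (one row per gene, allele `01`), carrying through coordinates,
#'   functionality and subgroup.
#' @export
assign_positional_names <- function(layout, subgroups = NULL, assoc = NULL) {
  g <- layout$genes
  if (is.null(assoc)) assoc <- associate_dj_to_c(layout)
  sub <- if (is.null(subgroups)) {
    stats::setNames(g$subgroup, g$id)
  } else if (inherits(subgroups, "igh_subgroups")) {
    subgroups$assignment
  } else subgroups
  dup <- layout$locus$locus_id == "B"
  sub <- unname(sub[g$id])          # align to layout rows; NA when missing
  names(sub) <- g$id
  v_idx <- which(g$group == "V")
  if (length(v_idx) && any(is.na(sub[g$id[v_idx]])))
    stop("missing subgroup for V gene(s): ",
         paste(g$id[v_idx][is.na(sub[g$id[v_idx]])], collapse = ", "),
         call. = FALSE)
  names_out <- rep(NA_character_, nrow(g))
  # V genes: 1..N by increasing distance from the most-3' cluster,
  # i.e. reversed biological order
  if (length(v_idx)) {
    pos <- rev(seq_along(v_idx))
    for (k in seq_along(v_idx)) {
      i <- v_idx[k]
      names_out[i] <- format_gene_name(gene_name(
        "V", subgroup = unname(sub[g$id[i]]), duplicated = dup,
        position = pos[k]))
    }
  }
  # dispersed D genes: hyphen positions in the same 3'->5' direction
  disp_ids <- assoc$id[assoc$assoc_c == "DISPERSED"]
  disp_idx <- which(g$id %in% disp_ids)
  if (length(disp_idx)) {
    pos <- rev(seq_along(disp_idx))
    for (k in seq_along(disp_idx))
      names_out[disp_idx[k]] <- format_gene_name(gene_name(
        "D", duplicated = dup, position = pos[k]))
  }
  # clustered D/J genes: per-cluster 5'->3' indices with the cluster tag
  members <- attr(assoc, "members")
  for (cid in names(members)) {
    ids <- members[[cid]]
    tag <- assoc$tag[match(ids[1], assoc$id)]
    for (grp in c("D", "J")) {
      ids_g <- ids[g$group[match(ids, g$id)] == grp]
      for (k in seq_along(ids_g)) {
        i <- match(ids_g[k], g$id)
        names_out[i] <- format_gene_name(gene_name(
          grp, duplicated = dup, cluster_index = k,
          c_tag = if (is.na(tag)) NA_character_ else tag))
      }
    }
  }
  # constant genes from isotype / tau series
  for (i in which(g$group == "C")) {
    iso <- g$isotype[i]
    names_out[i] <- format_gene_name(gene_name(
      "C", isotype = iso, duplicated = dup,
      subgroup = if (identical(iso, "T")) g$tau_series[i] else NA_integer_))
  }
  if (anyNA(names_out))
    stop("unnamed gene(s): ", paste(g$id[is.na(names_out)], collapse = ", "),
         call. = FALSE)
  out <- data.frame(
    name = names_out,
    species = layout$locus$species,
    locus_id = layout$locus$locus_id,
    chromosome = layout$locus$chromosome,
    start = g$start, stop = g$stop,
    polarity = g$polarity,
    subgroup = ifelse(g$group == "V", as.integer(unname(sub[g$id])),
                      NA_integer_),
    allele = "01",
    functionality = if ("functionality" %in% names(g)) g$functionality else "",
    in_frame = if ("in_frame" %in% names(g)) g$in_frame else FALSE,
    id = g$id,
    stringsAsFactors = FALSE)
  class(out) <- c("igh_gene_table", "data.frame")
  out
}

#' Distance-from-cluster rank of V genes on a locus
#'
#' Utility for checking printed positional numbers against coordinates:
#' rank 1 is the V gene nearest the 3' cluster end of the locus.
#'
#' @param start numeric start coordinates of the V genes.
#' @param orientation `"FWD"` or `"REV"`.
#' @return integer ranks.
#' @export
v_distance_rank <- function(start, orientation = c("FWD", "REV")) {
  orientation <- match.arg(orientation)
  if (orientation == "FWD") rank(-start, ties.method = "first")
  else rank(start, ties.method = "first")
}

.gff3_type <- c(V = "V_gene_segment", D = "D_gene_segment",
                J = "J_gene_segment", C = "C_gene_segment")

#' Write a named locus as GFF3
#'
#' Feature types `V_gene_segment`, `D_gene_segment`, `J_gene_segment`,
#' `C_gene_segment`; coordinates 1-based; strand from the locus orientation
#' combined with per-gene polarity.
#'
#' @param table an `igh_gene_table` with assigned names.
#' @param path output file.
#' @param orientation locus orientation used for strand computation.
#' @return `path`, invisibly.
#' @export
write_locus_gff3 <- function(table, path, orientation = "FWD") {
  grp <- vapply(table$name, function(n) parse_gene_name(n)$group, "")
  fwd <- orientation == "FWD"
  same <- table$polarity %in% c("same", "", NA)
  strand <- ifelse(xor(!fwd, !same), "-", "+")
  lines <- c("##gff-version 3",
             sprintf("%s\tsalmigh\t%s\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s;locus=%s",
                     table$chromosome, .gff3_type[grp],
                     table$start, table$stop, strand,
                     table$name, table$name, table$locus_id))
  writeLines(lines, path)
  invisible(path)
}
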