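#' VDJ repertoire annotation
#'
#' Annotates rearranged IGH reads against reference directories: V
#' assignment by local alignment on both strands with co-optimal ties
#' preserved (duplicated loci routinely hold genes with identical or
#' near-identical sequences, so ambiguity is reported, never silently
#' broken), J assignment downstream of the V match, junction delimitation
#' from the V-REGION 2nd-CYS codon (unique-numbering position 104) through
#' the J-REGION W/F codon (118), CDR3 as positions 105-117, D assignment by
#' longest exact forward-strand substring match, productivity calling, UMI
#' consensus deduplication, and usage/clonotype summaries with fractional
#' counting of ties.
#'
#' @name repertoire
NULL

.vj_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- Biostrings::nucleotideSubstitutionMatrix(
        match = 2, mismatch = -2, baseOnly = FALSE)
    cache
  }
})

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

.align_set <- function(patterns, subject) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), subject, type = "local",
    substitutionMatrix = .vj_submat(), gapOpening = 4, gapExtension = 1)
}

.dir_group_entries <- function(directory, group) {
  e <- directory$entries
  e <- e[.row_group(e$gene) == group, , drop = FALSE]
  if (nrow(e) == 0L || any(is.na(e$sequence)))
    stop("directory must hold ", group, " entries with sequences",
         call. = FALSE)
  e
}

#' Assign the V gene of a read
#'
#' Local alignment of the read (both strands) against every V allele of the
#' directory. All co-optimal hits by score are returned; a multi-hit result
#' is an ambiguous call.
#'
#' @param read nucleotide read (>= 100 nt recommended).
#' @param directory an `igh_refdir` with V sequences.
#' @param identity_floor best-hit identity below this flags the read as
#'   unassigned (default 0.60); flagged, not an error.
#' @return list: `hits` (data.frame of co-optimal hits: allele, gene,
#'   score, identity, locus_id, functionality, and the alignment
#'   coordinates on read and allele), `orientation` (`"+"`/`"-"`),
#'   `read` (plus-orientation sequence), `unassigned`.
#' @export
assign_v <- function(read, directory, identity_floor = 0.60) {
  read <- .check_nt(read, "read")
  v_e <- .dir_group_entries(directory, "V")
  score_of <- function(subject) .align_set(v_e$sequence, subject)
  aln_f <- score_of(read)
  rc <- .revcomp(read)
  aln_r <- score_of(rc)
  use_rev <- max(Biostrings::score(aln_r)) > max(Biostrings::score(aln_f))
  aln <- if (use_rev) aln_r else aln_f
  oriented <- if (use_rev) rc else read
  sc <- Biostrings::score(aln)
  best <- max(sc)
  top <- which(sc >= best - 1e-9)
  pid <- Biostrings::pid(aln, type = "PID1") / 100
  hits <- data.frame(
    allele_ref = v_e$allele_ref[top],
    gene = v_e$gene[top],
    score = sc[top],
    identity = pid[top],
    locus_id = v_e$locus_id[top],
    functionality = v_e$functionality[top],
    pattern_start = Biostrings::start(Biostrings::pattern(aln))[top],
    pattern_end = Biostrings::end(Biostrings::pattern(aln))[top],
    read_start = Biostrings::start(Biostrings::subject(aln))[top],
    read_end = Biostrings::end(Biostrings::subject(aln))[top],
    stringsAsFactors = FALSE)
  hits <- hits[order(-hits$score, -hits$identity, hits$allele_ref), ,
               drop = FALSE]
  rownames(hits) <- NULL
  list(hits = hits, orientation = if (use_rev) "-" else "+",
       read = oriented, unassigned = max(hits$identity) < identity_floor)
}

# last in-frame TGT/TGC codon = the 2nd-CYS (position 104) codon
.find_cys104 <- function(vseq) {
  n_aa <- nchar(vseq) %/% 3L
  codons <- substring(vseq, 3L * seq_len(n_aa) - 2L, 3L * seq_len(n_aa))
  hits <- which(codons %in% c("TGT", "TGC"))
  if (!length(hits)) return(NA_integer_)
  3L * hits[length(hits)] - 2L
}

.longest_common_substring <- function(a, b) {
  # returns max length of a shared substring (classic DP, strings are short)
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  if (!length(x) || !length(y)) return(0L)
  prev <- integer(length(y))
  best <- 0L
  for (i in seq_along(x)) {
    cur <- integer(length(y))
    for (j in seq_along(y)) {
      if (x[i] == y[j]) {
        cur[j] <- if (j == 1L) 1L else prev[j - 1L] + 1L
        if (cur[j] > best) best <- cur[j]
      }
    }
    prev <- cur
  }
  best
}

#' Delimit the junction and assign J and D
#'
#' The junction runs from the V-REGION 2nd-CYS codon (position 104),
#' located as the last in-frame cysteine codon of the matched V germline
#' and mapped onto the read through the V alignment, to the end of the
#' J-REGION W/F codon (position 118) located by the W/F-G-x-G motif.
#' CDR3 is the junction minus its bounding codons. The D gene is the
#' D-REGION with the longest exact forward-strand substring match of at
#' least `min_d_length` nt inside the CDR3; with no qualifying match the D
#' call is omitted.
#'
#' @param read plus-orientation read.
#' @param v_hit one row of [assign_v()] hits (the top hit).
#' @param directory an `igh_refdir` with V, D, J sequences.
#' @param min_d_length minimum retained D length for a call (default 5).
#' @param j_score_floor minimum local-alignment score for a J call; below
#'   it the read is incomplete.
#' @return list: `j_call`, `d_call` (`NA` when omitted; co-longest matches
#'   comma-joined), `d_ties`, `junction`, `junction_aa`, `cdr3`,
#'   `junction_start`, `junction_end`.
#' @export
analyze_junction <- function(read, v_hit, directory, min_d_length = 5,
                             j_score_floor = 20) {
  v_e <- .dir_group_entries(directory, "V")
  j_e <- .dir_group_entries(directory, "J")
  d_e <- .dir_group_entries(directory, "D")
  vseq <- v_e$sequence[match(v_hit$allele_ref, v_e$allele_ref)]
  cys <- .find_cys104(vseq)
  if (is.na(cys) || cys < v_hit$pattern_start)
    stop("cannot locate the 2nd-CYS codon of ", v_hit$allele_ref,
         call. = FALSE)
  jstart <- v_hit$read_start + (cys - v_hit$pattern_start)
  # J: best local alignment of the read portion downstream of the V match
  tail_from <- v_hit$read_end + 1L
  if (tail_from > nchar(read) - 10L)
    stop("no sequence downstream of the V match for a J call", call. = FALSE)
  tail_seq <- substring(read, tail_from)
  aln <- .align_set(j_e$sequence, tail_seq)
  sc <- Biostrings::score(aln)
  bi <- which.max(sc)
  if (sc[bi] < j_score_floor)
    stop("no J hit above the score floor (best ", round(sc[bi], 1), ")",
         call. = FALSE)
  jseq <- j_e$sequence[bi]
  w_off <- find_wgxg(jseq)
  if (is.na(w_off))
    stop("matched J-REGION lacks the W/F-G-x-G motif", call. = FALSE)
  j_pat_start <- Biostrings::start(Biostrings::pattern(aln))[bi]
  j_read_start <- tail_from - 1L + Biostrings::start(Biostrings::subject(aln))[bi]
  jend <- j_read_start + (w_off - j_pat_start) + 2L
  if (jend > nchar(read) || jend <= jstart)
    stop("junction boundaries fall outside the read", call. = FALSE)
  junction <- substr(read, jstart, jend)
  cdr3 <- if (nchar(junction) > 6L)
    substr(junction, 4L, nchar(junction) - 3L) else ""
  # D: longest exact substring against every D-REGION, searched in the
  # junction segment between the V and J germline contributions (the
  # N-D region); germline V/J junction bases never feed the D search
  d_call <- NA_character_
  d_ties <- character()
  # V/J local alignments can chance-extend a few bases into the N region;
  # pad the window so an eroded true D segment stays searchable
  nd_pad <- 3L
  nd_from <- max(jstart, v_hit$read_end + 1L - nd_pad)
  nd_to <- min(jend, j_read_start - 1L + nd_pad)
  nd_region <- if (nd_to >= nd_from) substr(read, nd_from, nd_to) else ""
  if (nzchar(nd_region)) {
    lens <- vapply(d_e$sequence, function(ds)
      .longest_common_substring(nd_region, ds), 0L, USE.NAMES = FALSE)
    if (max(lens) >= min_d_length) {
      # co-longest matches are reported together, like tied V calls
      d_ties <- d_e$allele_ref[lens == max(lens)]
      d_call <- paste(d_ties, collapse = ",")
    }
  }
  list(j_call = j_e$allele_ref[bi], d_call = d_call, d_ties = d_ties,
       junction = junction, junction_aa = translate_nt(junction),
       cdr3 = cdr3, junction_start = jstart, junction_end = jend)
}

#' Call productivity of a rearrangement
#'
#' Productive means: junction length divisible by 3, the junction
#' translation carries no stop codon, and the junction is anchored on the
#' V-REGION cysteine (so the V frame runs continuously into the J frame).
#'
#' @param junction_nt junction nucleotide sequence (positions 104-118).
#' @return list: `productive` (logical), `reasons` (character vector of
#'   `OUT_OF_FRAME`, `STOP_IN_JUNCTION`, `NO_JUNCTION_CYS`).
#' @export
call_productivity <- function(junction_nt) {
  reasons <- character()
  if (is.na(junction_nt) || !nzchar(junction_nt))
    return(list(productive = FALSE, reasons = "NO_JUNCTION"))
  if (nchar(junction_nt) %% 3L != 0L) reasons <- c(reasons, "OUT_OF_FRAME")
  aa <- translate_nt(junction_nt)
  if (grepl("\\*", aa)) reasons <- c(reasons, "STOP_IN_JUNCTION")
  if (!startsWith(aa, "C")) reasons <- c(reasons, "NO_JUNCTION_CYS")
  list(productive = length(reasons) == 0L, reasons = reasons)
}

#' Collapse reads sharing a UMI into consensus molecules
#'
#' Reads are grouped by exact UMI. Groups whose members share one length
#' are collapsed by per-column majority vote (ties keep the first read's
#' base); mixed-length groups are represented by their longest member.
#'
#' @param reads named character vector of reads.
#' @param umis character vector of UMIs, parallel to `reads`, all the same
#'   length.
#' @return data.frame: `umi`, `sequence`, `size`.
#' @export
dedup_umi <- function(reads, umis) {
  if (length(reads) != length(umis))
    stop("reads and umis must be parallel", call. = FALSE)
  if (length(unique(nchar(umis))) > 1L)
    stop("ragged UMI lengths", call. = FALSE)
  groups <- split(unname(reads), umis)
  out <- lapply(names(groups), function(u) {
    rs <- groups[[u]]
    if (length(unique(nchar(rs))) == 1L) {
      mat <- do.call(rbind, strsplit(rs, ""))
      cons <- apply(mat, 2, function(col) {
        tb <- table(factor(col, levels = unique(col)))
        names(tb)[which.max(tb)]
      })
      seq <- paste(cons, collapse = "")
    } else {
      seq <- rs[which.max(nchar(rs))]
    }
    data.frame(umi = u, sequence = seq, size = length(rs),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Annotate a set of repertoire reads
#'
#' Per-read pipeline [assign_v()] then [analyze_junction()] then
#' [call_productivity()]; per-read failures are recorded in the `status`
#' column and never abort the batch.
#'
#' @param reads named character vector (or `DNAStringSet`) of reads.
#' @param directory an `igh_refdir` holding V, D and J entries with
#'   sequences.
#' @param min_d_length,identity_floor,j_score_floor see the per-step
#'   functions.
#' @return a data.frame of class `igh_rearrangements`, one row per read:
#'   `sequence_id`, `v_call` (comma-joined co-optimal alleles), `d_call`,
#'   `j_call`, `junction`, `junction_aa`, `cdr3`, `productive`, `locus`
#'   (`A`/`B`/`ambiguous`), `v_identity`, `rev_comp`,
#'   `v_functionality`, `status` (`assigned`, `ambiguous`, `unassigned`,
#'   `incomplete`). `attr(, "summary")` counts the statuses.
#' @export
annotate_repertoire <- function(reads, directory, min_d_length = 5,
                                identity_floor = 0.60, j_score_floor = 20) {
  nm <- names(reads)
  reads <- stats::setNames(as.character(reads), nm)
  if (is.null(names(reads)) || !all(nzchar(names(reads))))
    names(reads) <- sprintf("read%05d", seq_along(reads))
  empty <- data.frame(
    sequence_id = character(), v_call = character(), d_call = character(),
    j_call = character(), junction = character(), junction_aa = character(),
    cdr3 = character(), productive = logical(), locus = character(),
    v_identity = numeric(), rev_comp = logical(),
    v_functionality = character(), status = character(),
    stringsAsFactors = FALSE)
  rows <- lapply(names(reads), function(id) {
    rec <- tryCatch({
      va <- assign_v(reads[[id]], directory, identity_floor)
      if (va$unassigned)
        return(data.frame(sequence_id = id, v_call = NA_character_,
                          d_call = NA_character_, j_call = NA_character_,
                          junction = NA_character_, junction_aa = NA_character_,
                          cdr3 = NA_character_, productive = FALSE,
                          locus = NA_character_,
                          v_identity = max(va$hits$identity),
                          rev_comp = va$orientation == "-",
                          v_functionality = NA_character_,
                          status = "unassigned", stringsAsFactors = FALSE))
      jn <- analyze_junction(va$read, va$hits[1, ], directory,
                             min_d_length, j_score_floor)
      prod <- call_productivity(jn$junction)
      loci <- unique(va$hits$locus_id)
      data.frame(
        sequence_id = id,
        v_call = paste(va$hits$allele_ref, collapse = ","),
        d_call = jn$d_call, j_call = jn$j_call,
        junction = jn$junction, junction_aa = jn$junction_aa,
        cdr3 = jn$cdr3, productive = prod$productive,
        locus = if (length(loci) == 1L) loci else "ambiguous",
        v_identity = va$hits$identity[1],
        rev_comp = va$orientation == "-",
        v_functionality = paste(unique(va$hits$functionality), collapse = ","),
        status = if (nrow(va$hits) > 1L) "ambiguous" else "assigned",
        stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(sequence_id = id, v_call = NA_character_,
                 d_call = NA_character_, j_call = NA_character_,
                 junction = NA_character_, junction_aa = NA_character_,
                 cdr3 = NA_character_, productive = FALSE,
                 locus = NA_character_, v_identity = NA_real_,
                 rev_comp = NA, v_functionality = NA_character_,
                 status = "incomplete", stringsAsFactors = FALSE))
    rec
  })
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  class(out) <- c("igh_rearrangements", "data.frame")
  attr(out, "summary") <- table(factor(
    out$status, levels = c("assigned", "ambiguous", "unassigned", "incomplete")))
  out
}

#' Write annotated rearrangements as an AIRR-style TSV
#'
#' Columns follow the AIRR Rearrangement naming (`sequence_id`, `v_call`,
#' `d_call`, `j_call`, `junction`, `junction_aa`, `cdr3`, `productive`,
#' `locus`, `v_identity`, `rev_comp`, `duplicate_count`).
#'
#' @param records an `igh_rearrangements` table.
#' @param path output file.
#' @param duplicate_count optional per-record duplicate counts (e.g. UMI
#'   group sizes).
#' @return `path`, invisibly.
#' @export
write_airr_tsv <- function(records, path, duplicate_count = NULL) {
  out <- as.data.frame(records)
  out$productive <- ifelse(out$productive, "T", "F")
  out$duplicate_count <- if (is.null(duplicate_count)) 1L else duplicate_count
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

.v_genes_of <- function(v_call) strsplit(v_call, ",", fixed = TRUE)[[1]] |>
  (\(x) unique(sub("\\*[0-9]+$", "", x)))()

#' V-gene usage of the productive repertoire
#'
#' Only productive records count. A record with k tied V genes contributes
#' 1/k to each (fractional counting); the per-locus share uses only records
#' whose locus call is unambiguous.
#'
#' @param records an `igh_rearrangements` table.
#' @return data.frame (`gene`, `count`, `pct`) sorted by usage;
#'   `attr(, "locus_share")` gives per-locus percentages,
#'   `attr(, "n_productive")` the record count.
#' @export
usage_table <- function(records) {
  prod <- records[which(records$productive), , drop = FALSE]
  if (nrow(prod) == 0L) stop("no productive records", call. = FALSE)
  acc <- new.env()
  for (vc in prod$v_call) {
    genes <- .v_genes_of(vc)
    for (g in genes)
      assign(g, (get0(g, envir = acc) %||% 0) + 1 / length(genes), envir = acc)
  }
  genes <- ls(acc)
  counts <- vapply(genes, get, 0, envir = acc)
  out <- data.frame(gene = genes, count = unname(counts),
                    pct = unname(100 * counts / sum(counts)),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  unamb <- prod[prod$locus %in% c("A", "B"), , drop = FALSE]
  share <- if (nrow(unamb))
    100 * table(unamb$locus) / nrow(unamb) else table(character())
  attr(out, "locus_share") <- share
  attr(out, "n_productive") <- nrow(prod)
  out
}

#' Aggregate productive records into clonotypes
#'
#' Clonotype key: V gene(s), J gene, CDR3 nucleotide sequence. Counts sum
#' to the number of productive records.
#'
#' @param records an `igh_rearrangements` table.
#' @return data.frame: `v_gene`, `j_gene`, `cdr3`, `count`, `sequence_ids`.
#' @export
aggregate_clonotypes <- function(records) {
  prod <- records[which(records$productive), , drop = FALSE]
  v_gene <- vapply(prod$v_call, function(v)
    paste(.v_genes_of(v), collapse = ","), "", USE.NAMES = FALSE)
  j_gene <- sub("\\*[0-9]+$", "", prod$j_call)
  key <- paste(v_gene, j_gene, prod$cdr3, sep = "\r")
  split_ids <- split(prod$sequence_id, key)
  parts <- strsplit(names(split_ids), "\r", fixed = TRUE)
  out <- data.frame(
    v_gene = vapply(parts, `[`, "", 1L),
    j_gene = vapply(parts, `[`, "", 2L),
    cdr3 = vapply(parts, `[`, "", 3L),
    count = vapply(split_ids, length, 1L),
    sequence_ids = vapply(split_ids, paste, "", collapse = ","),
    stringsAsFactors = FALSE)
  out <- out[order(-out$count), , drop = FALSE]
  rownames(out) <- NULL
  out
}
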