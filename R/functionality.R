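#' Functionality calling, RSS detection and V-REGION gapping
#'
#' Germline alleles are classed as functional (F), open reading frame (ORF),
#' or pseudogene (P). A pseudogene call requires a coding defect in the
#' V-REGION itself: an in-frame stop codon, an indel breaking the reading
#' frame, a defective initiation context, or truncation. An ORF call means
#' the reading frame is open but a flanking element (recombination signal,
#' splice site) or one of the conserved anchor residues (1st-CYS 23,
#' CONSERVED-TRP 41, hydrophobic 89, 2nd-CYS 104) is defective. A pseudogene
#' is "in frame" when its frame is open (stop codon or flanking defect only,
#' no frameshift); only in-frame pseudogenes are eligible for the extended
#' reference directory set.
#'
#' @name functionality
NULL

.rss_heptamer <- "CACAGTG"
.rss_nonamer <- "ACAAAAACC"
.hydrophobic <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")

.hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

#' Translate a nucleotide sequence
#'
#' Standard-code translation of complete codons; partial trailing codons are
#' dropped, codons containing N translate to `X`, stops render as `*`.
#'
#' @param nt nucleotide string.
#' @return amino-acid string.
#' @export
translate_nt <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Scan a flanking sequence for a recombination signal sequence
#'
#' Looks for the heptamer (consensus `CACAGTG`; the first three bases `CAC`
#' are required exact) followed, at the expected spacer length plus or minus
#' one, by the nonamer (consensus `ACAAAAACC`). V genes use a 23-nt spacer,
#' D genes 12-nt spacers on both flanks, J genes a 23-nt spacer. The
#' lowest-total-mismatch hit within `max_mismatch` per element wins.
#'
#' @param flank nucleotide string, at least heptamer + spacer + nonamer long.
#' @param expected_spacer 12 or 23.
#' @param max_mismatch maximum mismatches allowed in each element
#'   (default 2; the exact-`CAC` seed is on top of this).
#' @return a list (`heptamer`, `spacer_length` — the nominal 12 or 23,
#'   `spacer_observed`, `nonamer`, `score` — total mismatch count, `offset`
#'   — 1-based position of the heptamer in the flank), or `NULL` when no
#'   qualifying hit exists.
#' @export
find_rss <- function(flank, expected_spacer, max_mismatch = 2) {
  flank <- .check_nt(flank, "flank")
  if (!expected_spacer %in% c(12L, 23L))
    stop("expected_spacer must be 12 or 23", call. = FALSE)
  min_len <- 7L + expected_spacer + 9L
  if (nchar(flank) < min_len)
    stop("flank shorter than heptamer + spacer + nonamer (", min_len, " nt)",
         call. = FALSE)
  best <- NULL
  for (i in seq_len(nchar(flank) - 6L)) {
    hept <- substr(flank, i, i + 6L)
    if (substr(hept, 1L, 3L) != "CAC") next
    hept_mm <- .hamming(substr(hept, 4L, 7L), substr(.rss_heptamer, 4L, 7L))
    if (hept_mm > max_mismatch) next
    for (sp in expected_spacer + (-1L:1L)) {
      j <- i + 7L + sp
      if (j + 8L > nchar(flank)) next
      non <- substr(flank, j, j + 8L)
      non_mm <- .hamming(non, .rss_nonamer)
      if (non_mm > max_mismatch) next
      score <- hept_mm + non_mm
      if (is.null(best) || score < best$score)
        best <- list(heptamer = hept, spacer_length = expected_spacer,
                     spacer_observed = sp, nonamer = non,
                     score = score, offset = i)
    }
  }
  best
}

#' Lay an amino-acid V-REGION onto unique-numbering positions 1-104
#'
#' The framework regions map 1:1 onto fixed position blocks (FR1 1-26,
#' FR2 39-55, FR3 66-104); CDR1 occupies positions 27-38 and CDR2 positions
#' 56-65, each filled from both ends toward the middle so that gaps sit at
#' the top of the loop. The conserved-Trp anchor at position 41 (third
#' residue of FR2) delimits CDR1; CDR2's length follows from the total
#' length. Anchor residues are checked at positions 23 (C), 41 (W),
#' 89 (hydrophobic) and 104 (C).
#'
#' @param aa translated V-REGION (no stop characters).
#' @return a list of class `igh_gapped_v`: `gapped_aa` (104 characters, `.`
#'   for gaps), `anchors` (named positions), `anchor_present` (named
#'   logicals), `cdr1_length`, `cdr2_length`.
#' @export
gap_v_region <- function(aa) {
  aa <- toupper(as.character(aa))
  if (grepl("[*.]", aa))
    stop("input must be an ungapped, stop-free amino-acid sequence",
         call. = FALSE)
  r <- strsplit(aa, "")[[1]]
  L <- length(r)
  if (L < 82L || L > 104L)
    stop("V-REGION of ", L, " aa cannot be laid out on positions 1-104",
         call. = FALSE)
  if (L >= 23L && r[23] != "C" && r[L] != "C")
    stop("neither CYS anchor (positions 23/104) can be placed", call. = FALSE)
  w_candidates <- which(r == "W")
  w_candidates <- w_candidates[w_candidates >= 29L & w_candidates <= 41L]
  place <- NULL
  for (w in w_candidates) {
    c1 <- w - 29L
    c2 <- L - 82L - c1
    if (c1 >= 0L && c1 <= 12L && c2 >= 0L && c2 <= 10L) {
      place <- c(c1, c2)
      break
    }
  }
  if (is.null(place))
    stop("cannot place the conserved-Trp anchor: no CDR1/CDR2 layout fits",
         call. = FALSE)
  c1 <- place[1]; c2 <- place[2]
  fill_loop <- function(res, width) {
    n <- length(res)
    out <- rep(".", width)
    n_front <- ceiling(n / 2)
    n_back <- n - n_front
    if (n_front > 0) out[seq_len(n_front)] <- res[seq_len(n_front)]
    if (n_back > 0) out[(width - n_back + 1L):width] <- res[(n_front + 1L):n]
    out
  }
  gapped <- c(r[1:26],
              fill_loop(if (c1 > 0) r[27:(26 + c1)] else character(), 12L),
              r[(27 + c1):(43 + c1)],
              fill_loop(if (c2 > 0) r[(44 + c1):(43 + c1 + c2)] else character(), 10L),
              r[(44 + c1 + c2):L])
  stopifnot(length(gapped) == 104L)
  anchors <- c("1st-CYS" = 23L, "CONSERVED-TRP" = 41L,
               "HYDROPHOBIC-89" = 89L, "2nd-CYS" = 104L)
  present <- c(gapped[23] == "C", gapped[41] == "W",
               gapped[89] %in% .hydrophobic, gapped[104] == "C")
  names(present) <- names(anchors)
  structure(list(gapped_aa = paste(gapped, collapse = ""),
                 anchors = anchors, anchor_present = present,
                 cdr1_length = c1, cdr2_length = c2),
            class = "igh_gapped_v")
}

#' Call the functionality of a germline allele
#'
#' @param v_region_nt V-REGION nucleotide sequence (required), or a list
#'   with fields `v_region_nt`, `leader_nt`, `flank_3p`.
#' @param leader_nt optional leader sequence; a leader that does not begin
#'   with `ATG` is a defective initiation context.
#' @param flank_3p optional 3' flanking sequence scanned for the
#'   recombination signal with [find_rss()].
#' @param expected_spacer RSS spacer for this gene type (23 for V genes).
#' @param min_length V-REGIONs shorter than this are called truncated
#'   pseudogenes (default 240 nt, i.e. 80 codons).
#' @param strict when `TRUE`, flanking-element defects (RSS, splice) on an
#'   otherwise open frame are classed as in-frame pseudogenes rather than
#'   ORF.
#' @return a list of class `igh_functionality`: `value` (`"F"`, `"ORF"`,
#'   `"P"`), `in_frame` (meaningful for P: `TRUE` unless frameshifted),
#'   `reasons` (defect codes).
#' @export
classify_functionality <- function(v_region_nt, leader_nt = NULL,
                                   flank_3p = NULL, expected_spacer = 23,
                                   min_length = 240, strict = FALSE) {
  if (is.list(v_region_nt)) {
    allele <- v_region_nt
    v_region_nt <- allele$v_region_nt
    if (is.null(leader_nt)) leader_nt <- allele$leader_nt
    if (is.null(flank_3p)) flank_3p <- allele$flank_3p
  }
  if (is.null(v_region_nt) || !nzchar(v_region_nt %||% ""))
    stop("v_region_nt is required for functionality calling", call. = FALSE)
  v <- .check_nt(v_region_nt, "v_region_nt")
  p_reasons <- character()
  if (nchar(v) %% 3L != 0L) p_reasons <- c(p_reasons, "FRAMESHIFT")
  aa <- translate_nt(v)
  if (grepl("\\*", aa)) p_reasons <- c(p_reasons, "STOP_CODON")
  if (!is.null(leader_nt) && nzchar(leader_nt) &&
      !startsWith(toupper(leader_nt), "ATG"))
    p_reasons <- c(p_reasons, "NO_INIT")
  if (nchar(v) < min_length) p_reasons <- c(p_reasons, "TRUNCATED")
  if (length(p_reasons))
    return(structure(list(value = "P",
                          in_frame = !"FRAMESHIFT" %in% p_reasons,
                          reasons = p_reasons),
                     class = "igh_functionality"))
  orf_reasons <- character()
  if (!is.null(flank_3p) && nzchar(flank_3p)) {
    hit <- find_rss(flank_3p, expected_spacer)
    if (is.null(hit)) orf_reasons <- c(orf_reasons, "RSS_DEFECT")
  }
  gapped <- tryCatch(gap_v_region(sub("\\*+$", "", aa)),
                     error = function(e) NULL)
  if (is.null(gapped) || !all(gapped$anchor_present))
    orf_reasons <- c(orf_reasons, "CONSERVED_AA_CHANGE")
  if (length(orf_reasons)) {
    flank_only <- all(orf_reasons %in% c("RSS_DEFECT", "SPLICE_DEFECT"))
    if (strict && flank_only)
      return(structure(list(value = "P", in_frame = TRUE,
                            reasons = orf_reasons),
                       class = "igh_functionality"))
    return(structure(list(value = "ORF", in_frame = NA, reasons = orf_reasons),
                     class = "igh_functionality"))
  }
  structure(list(value = "F", in_frame = NA, reasons = character()),
            class = "igh_functionality")
}

#' @export
print.igh_functionality <- function(x, ...) {
  cat("<functionality> ", x$value,
      if (identical(x$value, "P")) paste0(" (in_frame = ", x$in_frame, ")"),
      if (length(x$reasons)) paste0(" [", paste(x$reasons, collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
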