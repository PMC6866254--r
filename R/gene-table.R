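#' Gene tables
#'
#' A gene table is the tabular projection of a set of located germline genes:
#' one row per allele, with columns `name`, `species`, `locus_id`,
#' `chromosome`, `start`, `stop`, `polarity`, `subgroup`, `allele`,
#' `functionality` and (optionally) `in_frame` for pseudogene alleles whose
#' V-REGION reading frame is open. Files are tab-separated, UTF-8, with `#`
#' comment lines.
#'
#' Coordinates are 1-based inclusive. A row printed with `start > stop`
#' encodes a gene whose polarity is opposite to the locus reading direction;
#' on load it is normalized to `(min, max)` and `polarity` is set to
#' `"opposite"`.
#'
#' @name gene-table
NULL

# Symbols occasionally printed with character-level slips (I/1 confusion,
# missing hyphens, stray tokens); normalized on load with a logged mapping.
.name_normalizations <- c(
  "IGHJIT4"       = "IGHJ1T4",
  "IGHJIT5"       = "IGHJ1T5",
  "IGHJID"        = "IGHJ1D",
  "IGHV12D56"     = "IGHV12D-56",
  "IGHV12D57"     = "IGHV12D-57",
  "IGH IGHV10-47" = "IGHV10-47"
)

#' Normalize gene symbols
#'
#' Applies the documented symbol normalizations (I/1 confusion, missing
#' hyphens, stray prefixes) and records which were touched.
#'
#' @param x character vector of gene symbols.
#' @return the normalized vector, with an attribute `normalized` giving a
#'   data.frame of `from`/`to` pairs actually applied.
#' @export
normalize_gene_names <- function(x) {
  hit <- x %in% names(.name_normalizations)
  log <- data.frame(from = x[hit],
                    to = unname(.name_normalizations[x[hit]]),
                    stringsAsFactors = FALSE)
  x[hit] <- .name_normalizations[x[hit]]
  attr(x, "normalized") <- log
  x
}

#' Read a gene table from TSV
#'
#' @param path file path.
#' @param normalize apply [normalize_gene_names()] to the `name` column
#'   (default `TRUE`).
#' @return a data.frame of class `igh_gene_table`. Attributes:
#'   `normalizations` (symbol fixes applied) and `polarity_normalized`
#'   (row indices whose printed coordinates were reversed).
#' @export
read_gene_table <- function(path, normalize = TRUE) {
  tbl <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("name", "locus_id", "start", "stop", "functionality")
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols))
    stop("gene table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("species", "chromosome", "polarity", "subgroup", "allele",
                "in_frame"))
    if (!col %in% names(tbl)) tbl[[col]] <- NA_character_
  norm_log <- data.frame(from = character(), to = character())
  if (normalize) {
    nm <- normalize_gene_names(tbl$name)
    norm_log <- attr(nm, "normalized")
    tbl$name <- as.character(nm)
  }
  tbl$start <- as.integer(gsub("[ ,]", "", tbl$start))
  tbl$stop <- as.integer(gsub("[ ,]", "", tbl$stop))
  tbl$subgroup <- suppressWarnings(as.integer(tbl$subgroup))
  tbl$allele <- ifelse(is.na(tbl$allele) | tbl$allele == "", "01", tbl$allele)
  tbl$in_frame <- toupper(trimws(tbl$in_frame)) %in% c("TRUE", "T", "1", "YES")
  rev_rows <- which(!is.na(tbl$start) & !is.na(tbl$stop) & tbl$start > tbl$stop)
  if (length(rev_rows)) {
    tmp <- tbl$start[rev_rows]
    tbl$start[rev_rows] <- tbl$stop[rev_rows]
    tbl$stop[rev_rows] <- tmp
    tbl$polarity[rev_rows] <- "opposite"
  }
  tbl$polarity[is.na(tbl$polarity) | tbl$polarity == ""] <- "same"
  class(tbl) <- c("igh_gene_table", "data.frame")
  attr(tbl, "normalizations") <- norm_log
  attr(tbl, "polarity_normalized") <- rev_rows
  tbl
}

#' Validate a gene table
#'
#' Row-by-row validation: the gene symbol must parse through the grammar,
#' functionality must be one of `F`, `ORF`, `P` or blank (blank is preserved
#' as "unstated", never guessed), coordinate intervals must have
#' `start != stop`, and for V genes the `subgroup` column must agree with the
#' subgroup encoded in the symbol.
#'
#' @param tbl a gene table (see [read_gene_table()]).
#' @return a validation report: data.frame with columns `row`, `field`,
#'   `message` (zero rows when the table is accepted) and attributes
#'   `accepted` (logical) and `unstated` (row indices with blank
#'   functionality).
#' @export
validate_gene_table <- function(tbl) {
  failures <- list()
  note <- function(row, field, message)
    failures[[length(failures) + 1L]] <<- data.frame(
      row = row, field = field, message = message, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tbl))) {
    gn <- tryCatch(parse_gene_name(tbl$name[i]), error = function(e) e)
    if (inherits(gn, "error")) {
      note(i, "name", conditionMessage(gn))
      gn <- NULL
    }
    fun <- trimws(tbl$functionality[i])
    if (is.na(fun)) fun <- ""
    if (!fun %in% c("F", "ORF", "P", ""))
      note(i, "functionality", paste0("functionality outside {F, ORF, P, blank}: '",
                                      fun, "'"))
    if (!is.na(tbl$start[i]) && !is.na(tbl$stop[i]) &&
        tbl$start[i] == tbl$stop[i])
      note(i, "coordinates", "zero-length interval (start == stop)")
    if (!is.null(gn) && gn$group == "V" && !is.na(tbl$subgroup[i]) &&
        tbl$subgroup[i] != gn$subgroup)
      note(i, "subgroup", paste0("subgroup column (", tbl$subgroup[i],
                                 ") disagrees with name (", gn$subgroup, ")"))
  }
  report <- if (length(failures)) do.call(rbind, failures) else
    data.frame(row = integer(), field = character(), message = character())
  attr(report, "accepted") <- nrow(report) == 0L
  attr(report, "unstated") <-
    which(is.na(tbl$functionality) | trimws(tbl$functionality) == "")
  report
}

#' Locate a packaged fixture table
#'
#' @param name file name under the package's `extdata` directory; with no
#'   argument, lists what is available.
#' @return a file path (or a character vector of available names).
#' @export
igh_fixture <- function(name = NULL) {
  dir <- system.file("extdata", package = "salmigh")
  if (is.null(name)) return(list.files(dir))
  path <- file.path(dir, name)
  if (!file.exists(path)) stop("no packaged fixture '", name, "'", call. = FALSE)
  path
}
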