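Package: salmigh
Title: Nomenclature, Classification and Repertoire Annotation for Duplicated
    Salmonid Immunoglobulin Heavy-Chain Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with the duplicated immunoglobulin heavy-chain
    (IGH) loci of salmonid fish (Atlantic salmon, rainbow trout). Implements
    the standardized germline gene-name grammar for duplicated A/B loci
    (locus-B "D" suffix, tau-cluster tags, dispersed diversity genes,
    provisional "S" names), V-gene subgroup classification by the 75 percent
    V-REGION nucleotide identity rule, IMGT-style functionality calling
    (F/ORF/P with in-frame pseudogene detection), recombination signal
    sequence scanning, positional gene naming along a locus, construction and
    FASTA serialization of filtered reference directory sets ("F+ORF",
    "F+ORF+in-frame P"), VDJ rearrangement annotation of repertoire reads
    with junction/CDR3 extraction and AIRR-style output, UMI consensus
    deduplication, germline variant tallying with silent/non-silent
    classification, UPGMA phylogenies with bootstrap support, and a seeded
    synthetic-locus and repertoire simulator with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    igraph,
    ape,
    phangorn,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
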