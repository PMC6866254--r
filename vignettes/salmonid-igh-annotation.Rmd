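---
title: "Annotating duplicated salmonid IGH loci: models, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating duplicated salmonid IGH loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Salmonid fish carry two large duplicated immunoglobulin heavy-chain (IGH)
loci per haplotype, a relic of the salmonid whole-genome tetraploidization.
Each locus holds hundreds of V genes (most of them pseudogenes), diversity
(D) and joining (J) genes organized in D-J-C clusters around the constant
genes of the IgM, IgD and IgT isotypes, plus dispersed D genes scattered
among the V genes. Annotating expressed antibody repertoires (AIRRseq)
against such loci requires three things this package provides: a consistent
gene nomenclature for duplicated loci, filtered germline reference
directories, and a rearrangement annotator that treats the ambiguity caused
by near-identical duplicated genes as a first-class outcome rather than an
error.

## The gene-name grammar

A symbol such as `IGHV6D-76` decomposes into group (`V`), subgroup (`6`),
the duplicated-locus flag (`D` = locus B), and the hyphenated position
(`76`) along the locus. D and J genes inside a D-J-C cluster carry an
unhyphenated cluster index and, when the cluster belongs to an IgT (tau)
constant gene, that gene's tag (`IGHD1T2D` = first D of the IGHT2D
cluster). A bare `IGHD` is the IgD (delta) constant gene; `IGHD` followed
by a digit or hyphen is a diversity gene — the grammar resolves this
deterministically. Provisional `S` names (`IGHV1S3`) mark genes known from
expression but not yet localized on an assembly. `parse_gene_name()` and
`format_gene_name()` are exact inverses; the suite verifies the round trip
on 10,000 random structurally valid names and on every packaged table.

One representational choice: the structured name keeps the numeric part of
a provisional `S` name in its own field (`s_number`), because the position
field is semantically "localized on the assembly", which provisional genes
by definition are not.

## Subgroups: the 75% identity rule

Two V genes belong to the same subgroup when their V-REGION nucleotide
sequences are at least 75% identical. The package computes identity on a
global alignment (match +1, mismatch 0, gap open −4, gap extend −1,
configurable) as identical columns over aligned columns after terminal-gap
columns are stripped. Because co-optimal alignments can differ slightly in
their identical-column count, the statistic is canonicalized — the pair is
evaluated in lexicographic order on both strands and the larger value kept —
so that identity is exactly symmetric and reverse-complement invariant.

Subgroup formation uses single linkage: subgroups are connected components
of the graph with an edge wherever identity reaches the threshold. This
matches the field's subgroup notion (membership is transitive through
intermediate sequences) and is declared in the output metadata; the suite
checks it against a brute-force component search on hundreds of random
matrices. De-novo labels are deterministic (components ordered by their
lexicographically smallest member); mapping de-novo clusters onto the
historical subgroup numbers 1–16 is done only through
`assign_to_reference_subgroups()` against a labeled directory, with ties
broken toward the lower subgroup number and flagged.

Whether the 75% rule should be applied to gapped or ungapped alignments is
not fixed by the nomenclature; the package defaults to the ungapped global
alignment above, and the scoring is exposed as arguments.

## Functionality calling

`classify_functionality()` applies a three-way decision:

* **P (pseudogene)** — a coding defect in the V-REGION itself: in-frame
  stop codon, length not a multiple of three (frameshift), defective
  initiation context (leader not starting `ATG`), or truncation below
  `min_length` (default 240 nt = 80 codons). `in_frame` is `TRUE` iff no
  frameshift: such in-frame pseudogenes are expressed in fish repertoires
  and belong in the extended reference directory.
* **ORF** — open frame but a defective flanking element (no qualifying
  recombination signal in the 3' flank) or a defective conserved anchor
  (positions 23, 41, 89, 104). The anchor check is limited to those four
  positions; broader framework conservation scoring is out of scope.
* **F** — everything else.

The boundary case — an open frame with only a flanking-element defect — is
classed ORF by default, following the standard functionality chart; a
`strict` switch reclassifies such alleles as in-frame P for workflows that
group RS defects with pseudogenes.

RSS detection (`find_rss()`) scans for the heptamer (consensus `CACAGTG`,
first three bases required exact — the `CAC` seed is near-invariant
biologically and keeps the search specific) followed by the nonamer
(`ACAAAAACC`) at the nominal spacer (23 for V, 12 for D flanks) ± 1, up to
2 mismatches per element, lowest total mismatch wins.

V-REGION gapping (`gap_v_region()`) lays the translated sequence onto
unique-numbering positions 1–104 with fixed framework blocks (FR1 1–26,
FR2 39–55, FR3 66–104) and CDR1/CDR2 filled from both ends toward the
middle of 27–38 / 56–65. This deterministic layout covers framework-regular
V regions (lengths 82–104 aa) and is what the functionality anchors are
read from; it does not attempt the full exception handling of a curated
numbering service (non-canonical framework insertions are out of scope).

## Positional nomenclature

`assign_positional_names()` encodes the numbering convention inferred from
the published coordinate/name correspondences: V position 1 is the V gene
closest to the mu D-J-C cluster, numbers increase 3' to 5' in one series
per locus shared by all subgroups, V genes between two clusters take the
smallest positions, and dispersed D genes are hyphen-numbered in the same
direction. Cluster D/J genes are numbered 1..k in 5'→3' order with their
cluster's tau tag. Cluster membership is defined purely by gene
interleaving — a D/J belongs to the nearest downstream C gene with no V
gene in between, with a per-gene override column for printed layouts where
a cluster's D genes sit downstream of their constant gene.

The published trout tables print two duplicate V position numbers (39 on
chromosome 13, 11 on chromosome 12), so printed positions are not a strict
1..N permutation. The suite therefore checks strict permutation and exact
rank agreement on simulator output, and monotone consistency (rank
correlation ≥ 0.999) on the transcribed trout coordinates.

## Reference directories

`build_directory()` filters per allele: `F_ORF` keeps functional and ORF
alleles; `F_ORF_INFRAME_P` adds in-frame pseudogene alleles; out-of-frame
pseudogenes never enter. A gene whose alleles differ in functionality
contributes exactly the alleles that pass (the functional `*02` of a gene
whose `*01` is a pseudogene enters the F+ORF set). Gene-mode summaries
count such genes once under their best functionality (F > ORF > P) and
also report the mixed genes separately, mirroring the dual "(+1)"
presentation of printed gene tables. Allele numbers are assigned in
registration order and never reused. The FASTA serialization uses a
reduced five-field pipe-delimited header
(`alleleref|species|functionality|locus|region`) — the fields the
downstream annotator consumes.

## Repertoire annotation

Reads are assigned a V by local alignment (match +2, mismatch −2, gap open
−4, extend −1) against every directory V allele on both strands; all
co-optimal hits are kept. Duplicated loci contain twin genes with identical
V-REGIONs, so a two-gene tie is a correct, informative call; usage tables
count a k-way tie as 1/k per gene (fractional counting — the declared
convention; first-gene counting would be the documented alternative).

The junction runs from the V-REGION 2nd-CYS codon (position 104; located
as the last in-frame cysteine codon of the matched germline and mapped
through the V alignment) to the end of the J-REGION W/F codon (position
118; located by the W/F-G-x-G motif). CDR3 is the junction minus its
bounding codons. D genes are assigned by the longest exact forward-strand
substring of at least 5 nt between a D-REGION and the junction segment
lying between the V and J germline contributions; co-longest matches are
reported together. Because local alignments can chance-extend a base or
two into untemplated N nucleotides, that segment is padded by 3 nt per
side — junction boundaries are identifiable only up to this parsimony
ambiguity, which is also why D recovery on simulated data is near-100%
rather than exactly 100% at every seed. Inverted D use is out of scope.

Productivity requires junction length divisible by three, a stop-free
junction translation, and the junction anchored on the V cysteine.
UMI deduplication groups reads by exact UMI and takes a per-column
majority consensus (equal-length groups) or the longest member.

## The simulator

`simulate_germline_locus()` generates what the classification and naming
machinery claims to handle, with ground truth:

* subgroup ancestors drawn by rejection sampling until all pairwise
  identities sit at or below the between-subgroup ceiling (default 0.65);
  members mutated from their ancestor at 1 − within-identity (default
  0.85). With the 0.75 threshold strictly between the two, single-linkage
  re-clustering recovers the planted partition exactly.
* functionality defects planted per configurable fractions: premature
  `TAA` (in-frame P) or a 1-nt deletion (out-of-frame P) for pseudogenes, a
  broken heptamer seed for ORF. Defaults (25% P, 12.5% ORF) keep a
  workable functional directory at desk scale; the real loci are far more
  pseudogene-heavy (roughly three quarters of salmon V genes), a regime
  the fixtures, not the simulator, represent.
* locus B as a per-gene diverged copy (default 2% per base) with the same
  planted classes, anchor and defect positions protected, and one twin
  pair kept sequence-identical by default — duplicated genes with
  identical V-REGIONs exist in the real loci and are the reason ambiguous
  calls must be preserved.
* one tau and one mu/delta D-J-C cluster per locus, dispersed D genes among
  the V genes, locus A reverse-oriented and locus B forward, mirroring the
  prototype loci. Every D gene across both loci gets its own
  5-mer-disjoint 18-nt sequence so the substring D search has a unique
  planted answer.
* rearrangements: V 3' trim 0–5 nt, D trims 0–6 nt per side, J 5' trim
  0–5 nt, geometric N additions (mean 3), uniform per-base substitutions at
  the configured rate, optional UMIs. V genes carry a 6-nt germline CDR3
  stub past the 2nd-CYS codon so that trimming consumes germline CDR3
  rather than the cysteine itself.

What the simulator does **not** emulate: somatic hypermutation hotspots
and lineages (mutations are uniform), P-nucleotides, gene conversion,
inverted D segments, sequencing-error profiles, and the extreme pseudogene
load of the real loci. Passing recovery tests therefore demonstrates the
machinery's correctness on clean, architecture-regular data, not
performance on real AIRRseq libraries.

All randomness derives from the configuration seed; identical
configurations give byte-identical output.

## Variants and trees

`tally_variants()` classifies SNPs by codon substitution in the gene's
reading frame (silent iff the amino acid is unchanged); variants on genes
without a defined frame (pseudogenes) count as SNPs but never as
non-silent. Class totals are plain sums over member genes, and the
packaged per-gene transcription reproduces the printed functional and
pseudogene totals for both trout chromosomes.

The published comparison of non-silent proportions between the two loci
names no test; the package reports Fisher's exact test (primary — the
counts are small) and the continuity-corrected chi-square (secondary),
with a significance flag at α = 0.05 that downstream code never consumes.

UPGMA trees use average-linkage `hclust` with node heights at half the
merged distance (ultrametric by construction; verified against a
brute-force implementation on small matrices). Distances for V-gene trees
are 1 − pairwise identity; bootstrap support resamples alignment columns
with replacement and reports clade frequency over replicates,
deterministically under a seed. Merge tie-breaking follows the clustering
library's deterministic order and is recorded in the tree metadata rather
than re-implemented.

## Problem sizes

The test-suite and the reproduction script run the simulator at desk scale
(2–3 subgroups of 3–4 genes, duplicated; 30–80 reads per repertoire,
1,000-name to 10,000-name grammar sweeps, 100–200 random matrices for the
clustering and UPGMA oracles), sizes chosen so that the full suite runs in
about two minutes on one core while still exercising every code path;
table-derived quantities are exact counts and independent of scale.

## Known limitations

* Junction boundaries are identifiable only up to parsimony: when an
  untemplated N base coincidentally continues the germline, it is
  indistinguishable from germline, and D calls adjacent to it inherit that
  ambiguity.
* The IMGT-style gapping handles framework-regular V regions only.
* Identity is alignment-parameter dependent; the defaults are declared and
  configurable but not the only defensible choice.
* The gene-level salmon and trout tables shipped as fixtures are synthetic
  expansions of per-subgroup summary counts (marked `synthetic` in their
  file names): every per-subgroup, per-locus, per-functionality count and
  allele multiplicity matches the published summaries, but individual
  gene names, positions and coordinates are placeholders.
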