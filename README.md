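# salmigh

Nomenclature, classification and repertoire annotation for the duplicated
immunoglobulin heavy-chain (IGH) loci of salmonid fish.

Salmonids (Atlantic salmon, rainbow trout) carry two large duplicated IGH
loci per haplotype — a relic of the salmonid whole-genome tetraploidization —
with hundreds of V genes per genome, most of them pseudogenes, and D-J-C
clusters for the IgM/IgD/IgT isotypes. Annotating expressed antibody
repertoires (AIRRseq) against these loci needs a consistent gene
nomenclature for the duplicated A/B loci, filtered germline reference
directories, and an annotator that reports — rather than hides — the
ambiguity created by near-identical duplicated genes. `salmigh` implements
that stack for immunogeneticists and repertoire bioinformaticians:

* **Gene-name grammar** — bidirectional parsing/rendering of salmonid IGH
  symbols: locus-B `D` suffix (`IGHV6D-76`), tau-cluster tags (`IGHD1T2D`),
  dispersed diversity genes (`IGHD-5`), the `IGHD`-vs-diversity-gene
  ambiguity, provisional `S` names.
* **Subgroup classification** — V genes form a subgroup when their
  V-REGION nucleotide identity is ≥ 75%; identity is computed on a global
  alignment and subgroups are the connected components (single linkage) of
  the threshold graph.
* **Functionality calling** — F / ORF / P with defect codes (stop,
  frameshift, initiation, truncation; recombination-signal and
  conserved-anchor defects), including the in-frame pseudogenes that fish
  repertoires express.
* **Positional nomenclature** — V position 1 nearest the mu D-J-C cluster,
  numbering 3'→5' in one series per locus; D/J cluster indices and tau
  tags; dispersed-D numbering; GFF3 output.
* **Reference directories** — the "F+ORF" and "F+ORF+in-frame P" filtered
  allele sets, FASTA serialization, allele registration with provisional
  `S` naming.
* **Repertoire annotation** — V/D/J assignment with co-optimal ties
  preserved, junction (positions 104–118) and CDR3 (105–117) extraction,
  productivity, UMI consensus, AIRR-style TSV, usage and clonotype tables
  with fractional counting of ties.
* **Variant tallies and trees** — silent/non-silent SNP classification,
  class totals, Fisher/chi-square proportion comparison, UPGMA trees with
  column-resampling bootstrap.
* **A seeded simulator** — duplicated loci with controlled subgroup
  identity structure, planted functionality defects and identical twin
  genes, plus V-D-J rearranged reads with trimming, N additions, mutations
  and UMIs, all with ground truth.

Packaged fixtures transcribe the published summary tables for the two
species (gene counts per subgroup and locus, directory composition,
per-gene variant counts across 19 isogenic trout lines), so the headline
numbers are reproducible offline in seconds.

## Worked example

```r
library(salmigh)

parse_gene_name("IGHD1T2D")   # first D gene of the IGHT2D (tau) cluster, locus B
#> <igh_gene_name> IGHD1T2D

# Atlantic salmon V-gene table: per-locus functionality counts
salmon <- read_gene_table(igh_fixture("salmon_ighv_genetable_synthetic.tsv"))
summarize_gene_table(salmon, "locus")
#>   locus_id  F ORF   P unstated Total
#> 1        A 30   7 108        0   145
#> 2        B 39   5 114        0   158
# 303 V genes in all: 145 on locus A, 158 on locus B, in 16 subgroups

# the extended reference directory: functional + ORF + in-frame pseudogene alleles
build_directory(salmon, "F_ORF_INFRAME_P")
#> <igh_refdir> 150 allele(s), set F_ORF_INFRAME_P, group V
#>   F ORF   P
#>  76  15  59

# simulate a duplicated locus and a 25-read repertoire, then re-annotate it
cfg <- sim_config(seed = 7, n_reads = 25)
sim <- simulate_germline_locus(cfg)
refdir <- sim_directory(sim)
rep <- simulate_repertoire(refdir, cfg)
ann <- annotate_repertoire(rep$reads, refdir)
attr(ann, "summary")
#>   assigned  ambiguous unassigned incomplete
#>         22          3          0          0
head(ann[, c("sequence_id", "v_call", "d_call", "j_call", "productive")], 4)
#>   sequence_id       v_call      d_call      j_call productive
#> 1   read00001 IGHV2D-12*01  IGHD2T1*01    IGHJ1*01      FALSE
#> 2   read00002   IGHV2-8*01  IGHD-2D*01    IGHJ2*01       TRUE
#> 3   read00003   IGHV3-3*01 IGHD1T1D*01   IGHJ2D*01       TRUE
#> 4   read00004  IGHV3D-1*01   IGHD-1*01 IGHJ1T1D*01      FALSE
```

The three `ambiguous` reads come from the simulator's planted identical
duplicate pair: both twin alleles are reported, and usage tables count the
tie fractionally. Non-productive records are out-of-frame junctions or
junctions containing a stop.

Variant tallies over the 19 isogenic trout lines, and the locus
comparison of silent vs non-silent SNPs:

```r
variant_class_totals(read_variant_summary(igh_fixture("trout_ighv_variants.tsv")))
#>   chromosome      class n_genes snp ns indel
#>        Chr12 functional      29  23 13     0
#>        Chr12 pseudogene      51  53 NA    10
#>        Chr13 functional      29  67 40     1
#>        Chr13 pseudogene      20  41 NA     3

compare_ns_proportions(rbind(c(40, 27), c(13, 10)))
#> <ns-proportion comparison> Fisher p = 0.8102 | chi-square = 0.0004765 (p = 0.9826); not significant at alpha = 0.05
```

A thin command-line front end over the same functions ships in
`inst/cli/igh.R` (subcommands `classify`, `build-refdir`, `annotate`,
`simulate`, `tally-variants`, `tree`).

## Scope

Out of scope by design: curation of real genome assemblies, light-chain
loci, somatic-hypermutation lineage inference, inverted D segments, and
graphical domain displays. The methods vignette
(`vignettes/salmonid-igh-annotation.Rmd`) documents the models,
conventions, parameter defaults and known limitations in detail.
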