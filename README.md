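# cinadapt

Tools for tracking how haploid yeast populations adapt to chromosomal
instability (CIN): karyotype calling from whole-genome sequencing read
depth, evolved-versus-ancestor mutation identification with coding-effect
classification, cohort aneuploidy and gene-set statistics, and the image
quantifications used for growth, minichromosome-loss and fluorescence
readouts. A synthetic-data module generates every input the pipeline
consumes — genomes, depth tracks, variant sets, plate and spindle images —
with known ground truth, so parameter recovery is testable end to end
without any external download.

## Who this is for

Groups running yeast experimental-evolution or CIN studies who sequence
strain collections and need reproducible, scriptable versions of the
standard readouts: which chromosomes are disomic, which mutations arose
during adaptation and what they do to proteins, whether mutated genes are
enriched for a phenotype category, and how strains score on plate and
microscopy assays.

## The core methods

**Karyotype from binned depth.** Per chromosome *c*, the mean per-bp depth
*d_c* over the 15 kb closest to each telomere is normalized by the
second-lowest-quartile reference *r* (mean of the values at ascending
ranks ⌈n/4⌉+1 … ⌈n/2⌉, i.e. ranks 5–8 of 16):

    k̂_c = d_c / r ,   disomic ⇔ k̂_c > 1.5  (strict)

The quartile reference is untouched by up to ⌈n/4⌉ disomies, and all calls
are invariant to rescaling counts. Segmental amplifications are maximal
runs (≥ 5 bins) of 4 kb bins with depth ratio > 1.5; partial-chromosome
segments ≥ 100 kb flag the strain for exclusion from cohort aneuploidy
summaries.

**Variants.** Keep substitutions with quality > 95 and depth on the
admissible side of a 300-read cutoff (direction configurable — see the
vignette), subtract every `(chrom, pos, alt)` seen in the ancestor, then
classify each surviving substitution on the gene's strand with the
standard code: silent / missense / nonsense / noncoding, with amino-acid
changes written like `S816X`.

**Cohort statistics.** Mean disomies per strain and per-chromosome
aneuploidy frequencies over non-excluded strains; exact hypergeometric
upper-tail enrichment of mutated genes in a CIN-related category
(p = Σ_{i≥k} C(K,i)·C(N−K,n−i)/C(N,n)); minichromosome transmission
fidelity as the selective/permissive colony ratio; unpaired t-tests
(pooled by default, Welch selectable).

**Images.** Perpendicular line scans with Gaussian fits (abundance proxy
A·σ·√(2π)), circle-minus-annulus background-corrected spot intensities,
growth as the thresholded fraction of a measurement circle, colony counts
as size-gated 8-connected components.

## Worked example

```r
library(cinadapt)

# a 16-chromosome synthetic genome and a strain disomic for chr05 + chr12
genome <- generate_genome(n_chrom = 16, length_range = c(60e3, 120e3),
                          gene_density = 0.5, seed = 1)
genome
#> <genome_model> 16 chromosomes (1,454,178 bp total), 727 genes

cn <- setNames(rep(1L, 16), names(chrom_lengths(genome)))
cn[c("chr05", "chr12")] <- 2L
track <- simulate_depth(genome, karyotype_truth(cn),
                        sim_config(seed = 2, coverage = 100))
calls <- call_karyotype(track)
head(as.data.frame(calls)[, c("chrom", "copy_number", "disomic")])
#>   chrom copy_number disomic
#> 1 chr01       1.006   FALSE
#> 2 chr02       1.013   FALSE
#> 3 chr03       0.969   FALSE
#> 4 chr04       1.002   FALSE
#> 5 chr05       2.045    TRUE
#> 6 chr06       1.023   FALSE
calls$chrom[calls$disomic]
#> [1] "chr05" "chr12"
```

Normalized copy number sits near 1 for euploid chromosomes and near 2 for
the simulated disomies; only the two true disomies exceed the strict 1.5
threshold.

```r
# evolved vs ancestor mutations, filtered, subtracted and annotated
vs <- simulate_variants(genome, n_ancestral = 8,
                        n_novel_by_class = c(missense = 3, nonsense = 1,
                                             silent = 2, noncoding = 2),
                        cfg = sim_config(seed = 3))
novel <- subtract_ancestor(filter_variants(vs$evolved),
                           filter_variants(vs$ancestor))
ann <- annotate_variants(novel, genome)
select_nonsynonymous(ann)[, c("chrom", "pos", "gene_id", "codon_change",
                              "aa_change", "effect")]
#>  chrom   pos gene_id codon_change aa_change   effect
#>  chr07 29318  G00289      AAG>ATG      K32M missense
#>  chr09 96498  G00433      GTA>CTA      V85L missense
#>  chr08 79381  G00374      CCG>CGG     P217R missense
#>  chr07 27985  G00288      TGG>TGA     W186X nonsense

# is a gene category over-represented among the hits?
set.seed(4)
gs <- gene_set(c("G00289", sample(genome$genes$gene_id, 119)),
               universe = genome$genes$gene_id)
cin_enrichment(c("G00289", "G00433", "G00374", "G00288"), gs)
#> <enrichment> 2 / 4 mutated genes in category (50.0%); K = 120, N = 727, p = 0.1292

format_percent(category_fraction(874, 6002))
#> [1] "14.5%"
```

The ancestor subtraction leaves exactly the eight simulated novel
mutations that pass the filters; the nonsynonymous table lists the three
missense and one nonsense changes with their codon and protein notation.
The enrichment line reads: 2 of 4 mutated genes fall in a 120-gene
category out of a 727-gene universe, upper-tail hypergeometric p = 0.13.
The last line is the category-fraction display convention for the
canonical 874-of-6,002 CIN-gene example.

An end-to-end cohort (simulate → karyotype → annotate → summarize →
enrich, with all inputs and outputs written to disk plus a JSON report)
is one call:

```r
report <- run_pipeline(run_config("out/", mode = "simulate", seed = 1))
```

A thin command-line front end over the same functions ships in
`inst/cli/cinadapt.R` (subcommands `run`, `karyotype`, `variants`,
`enrich`).

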