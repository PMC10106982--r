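---
title: "Methods: read-depth karyotyping, variant effects and cohort statistics for CIN adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: read-depth karyotyping, variant effects and cohort statistics for CIN adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cinadapt)
```

# Scope

`cinadapt` implements the computational analyses used to track how haploid
yeast populations adapt to chromosomal instability (CIN): whole-chromosome
and segmental copy-number calls from binned sequencing depth,
evolved-versus-ancestor mutation identification with coding-effect
classification, cohort-level aneuploidy and gene-set statistics, and the
image quantifications used for growth, minichromosome-loss and
fluorescence readouts. Everything runs on synthetic inputs with known
ground truth, so each estimator's recovery behavior is testable without
any external data. Read alignment and pileup-level variant calling are
deliberately upstream of this package: it consumes binned depth
(bedGraph) and variant records (VCF), not reads.

# Karyotype calling from binned depth

## Model

A haploid strain's chromosome *c* is summarized by its telomere-proximal
mean depth $d_c$ (reads/bp). Only a fixed window at the chromosome ends
enters $d_c$ — by default the 15 kb closest to each telomere — which
equalizes sampling across chromosomes of very different lengths and
reduces the influence of interstitial segmental events on the
whole-chromosome call. The euploid reference $r$ is the mean of the $d_c$
whose ascending rank falls in the second quartile (ranks
$\lceil n/4\rceil + 1 \dots \lceil n/2 \rceil$; ranks 5–8 of 16). The
normalized copy number is $\hat{k}_c = d_c / r$, and a chromosome is
called disomic when $\hat{k}_c > 1.5$ — strictly, so a value of exactly
1.5 stays euploid.

The second-lowest-quartile reference is the load-bearing robustness
choice: in a strain with up to $\lceil n/4 \rceil$ disomies the doubled
chromosomes occupy the top ranks and leave the reference untouched, and
because both $d_c$ and $r$ are linear in sequencing effort every call is
invariant under rescaling all counts by any constant.

## Parameters

| parameter | default | units | why |
|---|---|---|---|
| `telomere_window` | 15,000 | bp | window per chromosome end; both ends pooled per bp |
| `ends` | `"both"` | — | symmetric sampling of the two telomeres; `"left"`/`"right"` selectable |
| `disomy_threshold` | 1.5 | ratio | midpoint between 1 and 2 copies; strict inequality |
| `reference_stat` | `"mean"` | — | mean over the quartile slice; `"median"` selectable |
| `segment_bin_size` | 4,000 | bp | resolution for segmental detection |
| `segment_ratio_threshold` | 1.5 | ratio | bin counts toward an amplified run when strictly above |
| `min_segment_bins` | 5 | bins | 20 kb minimum event, suppressing single-bin noise |
| `large_segment_length` | 100,000 | bp | partial-chromosome events at least this long exclude a strain from cohort aneuploidy summaries |

Whether one or both telomeres entered the original per-chromosome value,
and whether the quartile slice was summarized by mean or median, are not
recoverable choices; both are exposed as options with the defaults above
(both ends, mean) on the grounds of symmetry and robustness.

If twice the window reaches the chromosome length the windows would
overlap, and the whole chromosome is used instead.

## Segmental amplifications

Larger segmental copy-number changes were originally a visual call on
4 kb-binned data. The package replaces the visual step with an explicit,
configurable rule: after re-binning to 4 kb, maximal runs of at least 5
consecutive bins whose per-bp depth ratio against a genome-wide
second-quartile reference strictly exceeds 1.5 are reported as segments.
A run spanning a whole chromosome is a disomy, not a segmental event; it
is marked `chrom_spanning` and never triggers the large-segment
exclusion flag. The 100 kb exclusion length is a declared default, not a
reconstruction — the original "large" criterion was visual.

# Variant filtering, subtraction and effect classification

Variant records (single-nucleotide substitutions with a phred-like
quality and a read depth) are kept when quality is strictly greater than
95 and depth is on the admissible side of a 300-read cutoff. The cutoff
direction is genuinely ambiguous in the source description; the default
mode `"max"` drops records *deeper* than 300 (collapsed repeats and
other pile-up artifacts produce spuriously deep, spuriously confident
calls at ~100× genome-wide coverage), and mode `"min"` is selectable for
the opposite reading. Records with no depth field fail closed by
default. Ancestor subtraction removes any record whose
`(chrom, pos, alt)` key occurs in the parent strain; the reference base
is validated against the genome but not used for matching.

Coding effects are classified on the gene's own strand with the standard
nuclear code: locate the codon containing the substitution, translate
reference and mutant codons, and call `silent` (same amino acid),
`nonsense` (stop gained) or `missense` (anything else, including
stop-loss — the classification vocabulary has no readthrough class).
Positions outside every gene are `noncoding`. Amino-acid changes are
reported in one-letter code with `X` for a stop (e.g. `S816X`). Genes
are single-exon by contract — introns are negligible in this yeast
context — which keeps the classifier exact and lets tests verify it
against a brute-force oracle that rebuilds and translates the entire
mutant CDS for every possible substitution of a fixture genome. The
oracle translates with the plain standard code (no alternative-initiator
special-casing), matching the per-codon table the classifier uses.

# Cohort statistics

*Aneuploidy summaries.* The mean number of disomic chromosomes per
strain and the per-chromosome fraction of disomic strains are computed
over non-excluded strains only; strains flagged for large segmental
amplifications drop out of both.

*Gene-set enrichment.* Whether mutated genes over-represent a CIN-related
category is tested with the exact hypergeometric upper tail:
$p = \sum_{i \ge k} \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}$ for $k$
of $n$ mutated genes in a category of $K$ out of $N$. Counting is
mutation-level by default (a gene hit in three strains contributes three
draws), matching how mutation tallies such as "26 of 98" are quoted;
`per_gene` counting, which matches the hypergeometric sampling model
exactly, is selectable. This in-package exact test deliberately replaces
external GO-enrichment tooling, so no FDR values from such tools are
reproduction targets; a Benjamini–Hochberg helper is provided for
batches. The category fraction helper reports the exact percentage
(`100*K/N`), with display truncated at one decimal — `format_percent`
renders 874/6,002 as `14.5%`, the convention used where that number is
quoted.

*Other readouts.* Minichromosome transmission fidelity is the selective
over permissive colony-count ratio, unclamped (values above 1 arise by
plating noise and are flagged, not hidden). Two-sample comparisons use
the unpaired t-test, Student's pooled-variance by default (the common
graphing-software default) with Welch selectable; two constant groups
with equal means resolve to $t = 0, p = 1$ by convention.

# Image quantification

*Line scans.* Profiles are sampled by bilinear interpolation along the
scan, averaged over a perpendicular width (default 3 px — the original
width is unstated; 3 px is a common ImageJ choice). A four-parameter
Gaussian $A e^{-(x-\mu)^2/2\sigma^2} + c$ is fitted by Levenberg–
Marquardt least squares with moment-based initialization (baseline from
the profile tails) and a small multi-start on $\sigma$, which prevents
the occasional collapse onto a single noise spike; $\sigma$ is bounded in
(0.5 px, profile length) and $c$ is free. The abundance proxy is the
baseline-free area $A\sigma\sqrt{2\pi}$. Non-convergence is reported via
a flag with `auc = NA`, never silently.

A note on attainable precision: with $A = 100$, $\sigma = 2$ px and
noise sd 5, the Cramér–Rao bound for the fitted AUC is ≈3.8% relative at
1 px profile sampling — no estimator can be within 5% of truth 95% of
the time at that density. The recovery tests therefore define their
fixture profiles at 0.2 px sampling (≈5× oversampling of the peak,
CRLB ≈ 1.7%), which is the regime interpolated line scans operate in;
this was fixed once as the fixture's study condition.

*Circle measurements.* Spot intensity is the inner-disk sum minus the
annulus-mean background times the inner pixel count; on a uniform image
the correction is exact and the result 0, and negative values are
reported as-is. For spot photometry the tests use a 3.5σ aperture with
the background annulus out to 8σ: 99.8% of a 2-D Gaussian's mass with
low summed-pixel noise, the usual aperture-photometry trade-off. Growth
is the percentage of pixels at or above a binarization threshold inside
a measurement circle. Colonies are 8-connected components of the
thresholded plate within explicit size gates (particle-analyzer
behavior varies with settings, so the gates are parameters, not
defaults hidden in code).

# The synthetic-data generator

The generator emulates, with known ground truth: a 16-chromosome haploid
genome with non-overlapping single-exon protein-coding genes on both
strands (every CDS starts ATG, ends at a stop, no internal in-frame
stops, so nonsense sites always exist); Poisson (optionally
negative-binomial) bin counts with mean `coverage × copy number ×
bin width / bin size`; ancestor/evolved variant sets where the evolved
set is the ancestor set plus exactly the requested novel mutations per
effect class, with quality/depth drawn to pass the default filters and,
on request, extra records deliberately on the failing side; Gaussian
spots on flat backgrounds and disk "colonies" for the image tools. One
root seed determines everything; sub-streams are derived per consumer
(`depth`, `variants`, image noise) so adding one stage never perturbs
another.

Default simulation conditions mirror the study system where stated:
16 chromosomes, up to 6 disomies per strain, a CIN-like category
covering ~15% of genes (874/6,002). Sequencing depth per strain is not
stated by the source beyond the platform, so the default coverage
(100 reads/bin at 1 kb bins; 50 in the recovery checks) is a free
parameter chosen to be comfortably within short-read practice — it is
not a reconstruction.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: GC- and mappability-driven coverage bias,
read-level error models, multi-exon genes, indels and multi-allelic
sites, subclonal (fractional) aneuploidy, uneven plate illumination, and
optical PSFs beyond an isotropic Gaussian. Noise after the additive
Gaussian stage is clamped at zero in synthetic images (camera counts are
non-negative), which slightly truncates the noise distribution near dark
backgrounds.

# Numerical and degenerate-input choices

- Depth bins are 0-based half-open (bedGraph convention); GFF3 and VCF
  coordinates are 1-based inclusive; conversions live only in I/O code.
- Telomere windows shorter than a bin are handled by overlap-weighted
  pro-rating of bin counts; last bins may be short and are width-scaled.
- `reference_depth` errors on fewer than 4 chromosomes or all-zero
  coverage rather than inventing a baseline; the segment detector's
  default genome-wide reference inherits this.
- A variant exactly at a filter threshold: quality 95 is dropped
  (strict), depth 300 is kept in mode `"max"` (cutoff is admissible).
- Tie-breaks in the quartile slice are rank-based (`sort`), so equal
  values are unambiguous.
- The Gaussian fit reports, rather than hides, non-convergence; profiles
  shorter than 5 samples are rejected.

# Problem sizes used by the test-suite and acceptance script

Recovery checks run at desk scale, chosen so the whole suite stays in
the minutes range: 100 simulated strains × 16 chromosomes at 50
reads/bin for karyotype recovery; every one of the ~30,000 possible
substitutions of a 10 kb two-strand fixture genome for the classifier
oracle; all hypergeometric instances with $N \le 12$ against subset
enumeration; 200 noisy profiles for AUC recovery; 50 simulated plates
for colony counting; 100 simulated 50-strain cohorts for enrichment
power. Cohort-level numbers from the original deposited sequencing data
(mutation totals, figure-level means) depend on that external dataset
and are not reproduction targets at this scale.

# Known limitations

- The karyotype caller assumes a haploid baseline with integer gains; it
  does not infer fractional clone mixtures or losses below one copy.
- Segment detection is a thresholded run-length rule standing in for a
  visual call; boundaries are bin-quantized and dips inside an amplified
  run split segments.
- The effect classifier requires single-exon, non-overlapping genes and
  single-nucleotide substitutions; indels are rejected at parse time.
- Mutation-level enrichment counting mildly violates the without-
  replacement null when the same gene is hit repeatedly; use `per_gene`
  counting when that matters.
- Image tools assume flat backgrounds within the measurement
  neighborhood; no illumination-field correction is applied.
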