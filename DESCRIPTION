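Package: cinadapt
Title: Karyotype Calling, Variant Annotation and Cohort Statistics for
    Yeast Adaptation to Chromosomal Instability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested, reusable pipeline for tracking how haploid yeast
    populations adapt to chromosomal instability (CIN). Calls
    whole-chromosome disomies and segmental amplifications from binned
    whole-genome-sequencing read depth using telomere-proximal windows and
    a second-lowest-quartile reference; filters and ancestor-subtracts
    variant calls and classifies coding effects (silent, missense,
    nonsense) against a FASTA/GFF3 genome; computes cohort aneuploidy
    summaries, exact hypergeometric gene-set enrichment for CIN-related
    genes, minichromosome transmission fidelity and unpaired t-tests; and
    quantifies fluorescence microscopy (perpendicular line scans with
    Gaussian fits, circle-based background subtraction) and plate images
    (growth area, colony counting). A synthetic-data generator produces
    genomes, depth tracks, variant sets and images with known ground truth
    so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    igraph,
    minpack.lm,
    jsonlite,
    tiff,
    png,
    tools,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
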