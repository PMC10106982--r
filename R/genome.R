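#' Genome model: chromosome sequences plus single-exon gene annotation
#'
#' The coordinate authority for the whole pipeline. Chromosome sequences are
#' held as a named [Biostrings::DNAStringSet]; genes are a data frame with
#' 1-based inclusive coordinates and a strand, each gene a single-exon CDS
#' (introns are negligible in the yeast context this models, and a
#' single-exon contract keeps the effect classifier exact).
#'
#' @param sequences Named `DNAStringSet` (or named character vector) of
#'   chromosome sequences over A/C/G/T.
#' @param genes Data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `strand` (`"+"` or `"-"`). May have zero rows.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(sequences, genes) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  if (!methods::is(sequences, "DNAStringSet"))
    stop("`sequences` must be a DNAStringSet or named character vector")
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("chromosome sequences must have unique names")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  required <- c("gene_id", "chrom", "start", "end", "strand")
  if (!all(required %in% names(genes)))
    stop("`genes` must have columns: ", paste(required, collapse = ", "))
  g <- structure(list(sequences = sequences, genes = genes),
                 class = "genome_model")
  validate_genome_model(g)
  g
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d chromosomes (%s bp total), %d genes\n",
              length(x$sequences),
              format(sum(Biostrings::width(x$sequences)), big.mark = ","),
              nrow(x$genes)))
  invisible(x)
}

#' Check all genome-model invariants
#'
#' Genes must lie within their chromosome, not overlap each other, have CDS
#' length divisible by three, and begin with a start codon and end with a
#' stop codon on their own strand.
#'
#' @param g A [genome_model()].
#' @return `g`, invisibly; stops with an informative error on violation.
#' @export
validate_genome_model <- function(g) {
  genes <- g$genes
  if (nrow(genes) == 0L) return(invisible(g))
  lens <- setNames(Biostrings::width(g$sequences), names(g$sequences))
  if (!all(genes$chrom %in% names(lens)))
    stop("gene(s) on unknown chromosome: ",
         paste(unique(setdiff(genes$chrom, names(lens))), collapse = ", "))
  bad <- genes$start < 1L | genes$end > lens[genes$chrom] | genes$start > genes$end
  if (any(bad))
    stop("gene interval out of chromosome bounds: ",
         paste(genes$gene_id[bad], collapse = ", "))
  if (any((genes$end - genes$start + 1L) %% 3L != 0L))
    stop("CDS length not divisible by 3 for: ",
         paste(genes$gene_id[(genes$end - genes$start + 1L) %% 3L != 0L],
               collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  for (chr in unique(genes$chrom)) {
    gc <- genes[genes$chrom == chr, , drop = FALSE]
    gc <- gc[order(gc$start), , drop = FALSE]
    if (nrow(gc) > 1L && any(gc$start[-1L] <= gc$end[-nrow(gc)]))
      stop("overlapping genes on ", chr)
  }
  cds <- gene_cds(g, genes$gene_id)
  first <- as.character(Biostrings::subseq(cds, 1L, 3L))
  n <- Biostrings::width(cds)
  last <- as.character(Biostrings::subseq(cds, n - 2L, n))
  if (!all(first == "ATG"))
    stop("CDS does not begin with ATG: ",
         paste(genes$gene_id[first != "ATG"], collapse = ", "))
  if (!all(last %in% c("TAA", "TAG", "TGA")))
    stop("CDS does not end with a stop codon: ",
         paste(genes$gene_id[!last %in% c("TAA", "TAG", "TGA")], collapse = ", "))
  invisible(g)
}

#' Extract strand-oriented CDS sequences for genes
#'
#' @param g A [genome_model()].
#' @param gene_ids Character vector of gene ids (default: all genes).
#' @return A `DNAStringSet` of CDS sequences, 5'→3' on the coding strand.
#' @export
gene_cds <- function(g, gene_ids = g$genes$gene_id) {
  idx <- match(gene_ids, g$genes$gene_id)
  if (anyNA(idx)) stop("unknown gene id(s): ",
                       paste(gene_ids[is.na(idx)], collapse = ", "))
  genes <- g$genes[idx, , drop = FALSE]
  seqs <- Biostrings::DNAStringSet(vapply(seq_len(nrow(genes)), function(i) {
    s <- as.character(Biostrings::subseq(g$sequences[[genes$chrom[i]]],
                                         genes$start[i], genes$end[i]))
    s
  }, character(1)))
  minus <- genes$strand == "-"
  if (any(minus))
    seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  names(seqs) <- genes$gene_id
  seqs
}

stop_codons <- c("TAA", "TAG", "TGA")

# All 61 sense codons (standard nuclear code).
sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all_codons, stop_codons)
}

#' Generate a random genome with non-overlapping single-exon genes
#'
#' Produces a synthetic stand-in for a haploid yeast genome: `n_chrom`
#' chromosomes of random length within `length_range`, carrying protein-coding
#' genes on both strands at roughly `gene_density` genes per kb. Every CDS
#' starts with ATG, ends with a stop codon, has length divisible by 3, and
#' contains no internal in-frame stop, so nonsense mutations are always
#' well-defined. Fully determined by `seed`.
#'
#' @param n_chrom Number of chromosomes (default 16, the yeast count).
#' @param length_range Two-element numeric, chromosome length bounds in bp.
#'   Lengths of at least 30 kb are recommended so the two 15 kb
#'   telomere-proximal windows used by the karyotype caller are disjoint.
#' @param gene_density Genes per kb (default 0.5, approximately the density
#'   of the 6,002 annotated yeast genes over a 12 Mb genome). `0` yields a
#'   gene-free genome.
#' @param gene_length_range Codon-count bounds per gene, start and stop
#'   codons included (default 60–400 codons).
#' @param seed Integer seed; the same seed yields a byte-identical genome.
#' @return A [genome_model()].
#' @export
generate_genome <- function(n_chrom = 16L,
                            length_range = c(120e3, 300e3),
                            gene_density = 0.5,
                            gene_length_range = c(60L, 400L),
                            seed = 1L) {
  stopifnot(n_chrom >= 1L, length(length_range) == 2L,
            length_range[1] >= 1e3, gene_density >= 0)
  with_seed(seed, {
    sense <- sense_codons()
    chrom_names <- sprintf("chr%02d", seq_len(n_chrom))
    lengths <- round(runif(n_chrom, length_range[1], length_range[2]))
    seq_list <- character(n_chrom)
    gene_rows <- list()
    gid <- 0L
    for (i in seq_len(n_chrom)) {
      L <- lengths[i]
      chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
      n_genes <- round(gene_density * L / 1000)
      if (n_genes > 0) {
        n_codons <- sample(seq(gene_length_range[1], gene_length_range[2]),
                           n_genes, replace = TRUE)
        gene_bp <- 3L * n_codons
        slack <- L - sum(gene_bp)
        if (slack < n_genes + 1L)
          stop(sprintf(
            "cannot pack %d genes (%d bp) into a %d bp chromosome at density %.3g",
            n_genes, sum(gene_bp), L, gene_density))
        # distribute the slack as random inter-gene gaps (each >= 1 bp)
        cuts <- sort(sample.int(slack - 1L, n_genes))
        gaps <- diff(c(0L, cuts, slack))
        pos <- 1L
        for (j in seq_len(n_genes)) {
          pos <- pos + gaps[j]
          start <- pos
          end <- pos + gene_bp[j] - 1L
          strand <- sample(c("+", "-"), 1L)
          body <- sample(sense, n_codons[j] - 2L, replace = TRUE)
          cds <- paste0("ATG", paste(body, collapse = ""),
                        sample(stop_codons, 1L))
          genomic <- if (strand == "+") cds else
            as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
          chars[start:end] <- strsplit(genomic, "")[[1]]
          gid <- gid + 1L
          gene_rows[[length(gene_rows) + 1L]] <- data.frame(
            gene_id = sprintf("G%05d", gid), chrom = chrom_names[i],
            start = start, end = end, strand = strand,
            stringsAsFactors = FALSE)
          pos <- end + 1L
        }
      }
      seq_list[i] <- paste(chars, collapse = "")
    }
    genes <- if (length(gene_rows)) do.call(rbind, gene_rows) else
      data.frame(gene_id = character(), chrom = character(),
                 start = integer(), end = integer(), strand = character(),
                 stringsAsFactors = FALSE)
    genome_model(setNames(seq_list, chrom_names), genes)
  })
}

#' Chromosome lengths of a genome model
#' @param g A [genome_model()].
#' @return Named integer vector of lengths in bp.
#' @export
chrom_lengths <- function(g) {
  setNames(Biostrings::width(g$sequences), names(g$sequences))
}

#' Write a genome model to FASTA and GFF3
#'
#' Gene features are written as GFF3 `gene` records with an `ID` attribute,
#' 1-based inclusive coordinates.
#'
#' @param g A [genome_model()].
#' @param fasta,gff3 Output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_genome <- function(g, fasta, gff3) {
  Biostrings::writeXStringSet(g$sequences, fasta)
  if (nrow(g$genes) > 0L) {
    gr <- GenomicRanges::GRanges(
      g$genes$chrom,
      IRanges::IRanges(g$genes$start, g$genes$end),
      strand = g$genes$strand, type = "gene", ID = g$genes$gene_id)
  } else {
    gr <- GenomicRanges::GRanges()
  }
  rtracklayer::export(gr, gff3, format = "gff3")
  invisible(list(fasta = fasta, gff3 = gff3))
}

#' Read a genome model from FASTA and GFF3
#'
#' Only features of type `gene` with an `ID` attribute are used.
#'
#' @param fasta,gff3 Input paths.
#' @return A [genome_model()].
#' @export
read_genome <- function(fasta, gff3) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gff3, format = "gff3")
  gr <- gr[gr$type == "gene"]
  genes <- data.frame(
    gene_id = as.character(gr$ID),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  genome_model(seqs, genes)
}
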