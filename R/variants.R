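#' Variant filter parameters
#'
#' Records are kept when their quality strictly exceeds `min_qual` and
#' their read depth lies on the admissible side of `depth_cutoff`. The
#' direction of the depth cutoff is ambiguous in common usage, so both are
#' provided: mode `"max"` (default) drops records deeper than the cutoff
#' (guarding against collapsed repeats and other pile-up artifacts), mode
#' `"min"` drops records shallower than it.
#'
#' @param min_qual Minimum quality, strict (default 95).
#' @param depth_cutoff Read-depth cutoff (default 300).
#' @param depth_mode `"max"` (keep depth <= cutoff, default) or `"min"`
#'   (keep depth >= cutoff).
#' @param missing_depth Policy for records with no depth: `"fail"`
#'   (default, record dropped and counted) or `"pass"`.
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(min_qual = 95, depth_cutoff = 300,
                          depth_mode = c("max", "min"),
                          missing_depth = c("fail", "pass")) {
  depth_mode <- match.arg(depth_mode)
  missing_depth <- match.arg(missing_depth)
  assert_scalar_number(min_qual, "min_qual", positive = TRUE)
  assert_scalar_number(depth_cutoff, "depth_cutoff", positive = TRUE)
  structure(list(min_qual = min_qual, depth_cutoff = depth_cutoff,
                 depth_mode = depth_mode, missing_depth = missing_depth),
            class = "filter_params")
}

#' Construct a table of single-nucleotide variant records
#'
#' @param chrom,pos,ref,alt,qual,depth Parallel vectors: chromosome,
#'   1-based position, reference and alternate base (single nucleotides),
#'   phred-like quality, read depth (NA allowed).
#' @return Data frame with those columns.
#' @export
variant_records <- function(chrom, pos, ref, alt, qual, depth = NA_real_) {
  if (length(chrom) == 0L)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), qual = numeric(), depth = numeric(),
                      stringsAsFactors = FALSE))
  v <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  ref = toupper(as.character(ref)),
                  alt = toupper(as.character(alt)),
                  qual = as.numeric(qual), depth = as.numeric(depth),
                  stringsAsFactors = FALSE)
  if (any(nchar(v$ref) != 1L | nchar(v$alt) != 1L))
    stop("only single-nucleotide substitutions are supported")
  if (any(v$ref == v$alt)) stop("ref and alt must differ")
  v
}

#' Filter variant records by quality and read depth
#'
#' Keeps records with `qual > min_qual` (strict) whose depth is admissible
#' under the configured cutoff mode; input order is preserved. Records
#' with missing depth follow the `missing_depth` policy and dropped ones
#' are counted in a message.
#'
#' @param records Variant data frame (see [variant_records()]).
#' @param params A [filter_params()].
#' @return The retained rows, original order.
#' @export
filter_variants <- function(records, params = filter_params()) {
  keep_qual <- records$qual > params$min_qual
  depth_ok <- if (params$depth_mode == "max")
    records$depth <= params$depth_cutoff else records$depth >= params$depth_cutoff
  missing <- is.na(records$depth)
  depth_ok[missing] <- params$missing_depth == "pass"
  n_missing_dropped <- sum(missing & keep_qual & params$missing_depth == "fail")
  if (n_missing_dropped > 0)
    message(n_missing_dropped,
            " record(s) without depth dropped (missing_depth = \"fail\")")
  records[keep_qual & depth_ok, , drop = FALSE]
}

variant_key <- function(records) {
  paste(records$chrom, records$pos, records$alt, sep = ":")
}

#' Subtract ancestral variants from an evolved strain's set
#'
#' Returns the evolved records whose `(chrom, pos, alt)` key does not occur
#' in the ancestor set, preserving order. The reference base is not part of
#' the key: it is validated against the genome at annotation time, not used
#' for matching.
#'
#' @param evolved,ancestor Variant data frames from the same genome.
#' @return Rows of `evolved` absent from `ancestor`.
#' @export
subtract_ancestor <- function(evolved, ancestor) {
  if (nrow(ancestor) == 0L) return(evolved)
  evolved[!variant_key(evolved) %in% variant_key(ancestor), , drop = FALSE]
}

#' Annotate variants with gene context and coding effect
#'
#' Each substitution is classified as `noncoding` (no gene overlaps its
#' position) or, within a gene, by translating the reference and mutant
#' codons on the gene's strand with the standard nuclear code: same amino
#' acid, `silent`; stop gained, `nonsense`; otherwise `missense` (stop-loss
#' is classified as missense). Amino-acid changes use one-letter code with
#' `X` for a stop, e.g. `S816X`.
#'
#' @param records Variant data frame (see [variant_records()]).
#' @param genome A [genome_model()].
#' @return The input plus columns `gene_id`, `codon_index`,
#'   `codon_change`, `aa_change` (NA for noncoding) and `effect`.
#' @export
annotate_variants <- function(records, genome) {
  n <- nrow(records)
  out <- records
  out$gene_id <- NA_character_
  out$codon_index <- NA_integer_
  out$codon_change <- NA_character_
  out$aa_change <- NA_character_
  out$effect <- rep("noncoding", n)
  if (n == 0L) return(out)

  lens <- chrom_lengths(genome)
  if (!all(records$chrom %in% names(lens)))
    stop("variant on unknown chromosome: ",
         paste(unique(setdiff(records$chrom, names(lens))), collapse = ", "))
  if (any(records$pos < 1L | records$pos > lens[records$chrom]))
    stop("variant position outside chromosome bounds")
  # validate the stated reference base against the genome
  chrom_chars <- lapply(genome$sequences, as.character)
  genome_ref <- vapply(seq_len(n), function(i)
    substr(chrom_chars[[records$chrom[i]]], records$pos[i], records$pos[i]),
    character(1))
  bad_ref <- genome_ref != records$ref
  if (any(bad_ref))
    stop("reference base disagrees with the genome at ",
         paste(sprintf("%s:%d (%s vs %s)", records$chrom[bad_ref],
                       records$pos[bad_ref], records$ref[bad_ref],
                       genome_ref[bad_ref])[seq_len(min(5, sum(bad_ref)))],
               collapse = ", "))

  genes <- genome$genes
  if (nrow(genes) == 0L) return(out)
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(records$chrom,
                           IRanges::IRanges(records$pos, records$pos)),
    GenomicRanges::GRanges(genes$chrom,
                           IRanges::IRanges(genes$start, genes$end)),
    ignore.strand = TRUE)
  vi <- S4Vectors::queryHits(hits)
  gi <- S4Vectors::subjectHits(hits)
  if (anyDuplicated(vi))
    stop("variant overlapping multiple genes: annotation invariant breached")
  code <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (k in seq_along(vi)) {
    i <- vi[k]; j <- gi[k]
    plus <- genes$strand[j] == "+"
    cds_pos <- if (plus) records$pos[i] - genes$start[j] + 1L else
      genes$end[j] - records$pos[i] + 1L
    codon_index <- (cds_pos - 1L) %/% 3L + 1L
    pos_in_codon <- (cds_pos - 1L) %% 3L + 1L
    cod_gstart <- if (plus) genes$start[j] + (codon_index - 1L) * 3L else
      genes$end[j] - codon_index * 3L + 1L
    codon_genomic <- substr(chrom_chars[[genes$chrom[j]]],
                            cod_gstart, cod_gstart + 2L)
    ref_codon <- if (plus) codon_genomic else
      paste(rev(comp[strsplit(codon_genomic, "")[[1]]]), collapse = "")
    alt_on_strand <- if (plus) records$alt[i] else comp[[records$alt[i]]]
    alt_codon <- ref_codon
    substr(alt_codon, pos_in_codon, pos_in_codon) <- alt_on_strand
    ref_aa <- code[[ref_codon]]
    alt_aa <- code[[alt_codon]]
    out$gene_id[i] <- genes$gene_id[j]
    out$codon_index[i] <- codon_index
    out$codon_change[i] <- paste0(ref_codon, ">", alt_codon)
    out$aa_change[i] <- paste0(chartr("*", "X", ref_aa), codon_index,
                               chartr("*", "X", alt_aa))
    out$effect[i] <-
      if (alt_aa == ref_aa) "silent"
      else if (alt_aa == "*" && ref_aa != "*") "nonsense"
      else "missense"
  }
  out
}

#' Classify the coding effect of a single variant
#'
#' Convenience wrapper around [annotate_variants()] for one record.
#'
#' @param v One-row variant data frame, or a list with fields `chrom`,
#'   `pos`, `ref`, `alt` (quality/depth optional).
#' @param genome A [genome_model()].
#' @return A one-row annotated data frame; see [annotate_variants()].
#' @export
classify_effect <- function(v, genome) {
  if (!is.data.frame(v))
    v <- variant_records(v$chrom, v$pos, v$ref, v$alt,
                         v$qual %||% NA_real_, v$depth %||% NA_real_)
  annotate_variants(v, genome)
}

#' Keep protein-changing variants
#'
#' Nonsynonymous mutations are those that alter the protein: missense
#' substitutions and nonsense (stop-gain) substitutions.
#'
#' @param annotated Output of [annotate_variants()].
#' @return The missense and nonsense rows, order preserved.
#' @export
select_nonsynonymous <- function(annotated) {
  annotated[annotated$effect %in% c("missense", "nonsense"), , drop = FALSE]
}

#' Read a minimal VCF into a variant table
#'
#' Uses the QUAL column for quality and `DP` from INFO for depth.
#' Non-SNV records (indels, multi-allelic rows, symbolic alleles) are
#' rejected with a warning giving the count dropped.
#'
#' @param path VCF v4.2 path (plain text).
#' @return Variant data frame (see [variant_records()]).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(variant_records(character(), integer(), character(), character(),
                           numeric(), numeric()))
  dp <- suppressWarnings(as.numeric(vcfR::extract.info(v, "DP")))
  snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  if (any(!snv))
    warning(sum(!snv), " non-SNV record(s) dropped from ", basename(path))
  variant_records(fix$CHROM[snv], as.integer(fix$POS[snv]), fix$REF[snv],
                  fix$ALT[snv], as.numeric(fix$QUAL[snv]), dp[snv])
}

#' Write a variant table as minimal VCF v4.2
#'
#' Plain-text output with CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO and the
#' depth in `INFO/DP`.
#'
#' @param records Variant data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=cinadapt",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  body <- if (nrow(records) > 0L) {
    info <- ifelse(is.na(records$depth), ".",
                   sprintf("DP=%d", as.integer(records$depth)))
    sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\t%s",
            records$chrom, records$pos, records$ref, records$alt,
            format(records$qual, trim = TRUE), info)
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}
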