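# Fixture builders and independent oracles shared across tests.

# Seeded evaluation without disturbing the session RNG.
with_seed_local <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Hand-built two-gene genome: one gene per strand at known coordinates.
#   G1 (+): ATG AAA TAA at 11..19
#   G2 (-): CDS ATG CCC TGA, genomic revcomp TCAGGGCAT at 31..39
toy_genome <- function() {
  chars <- rep("C", 60)
  chars[11:19] <- strsplit("ATGAAATAA", "")[[1]]
  chars[31:39] <- strsplit("TCAGGGCAT", "")[[1]]
  genome_model(
    c(chrA = paste(chars, collapse = "")),
    data.frame(gene_id = c("G1", "G2"), chrom = "chrA",
               start = c(11L, 31L), end = c(19L, 39L),
               strand = c("+", "-"), stringsAsFactors = FALSE))
}

# Uniform-depth track: `rate` reads/bp on every chromosome.
uniform_track <- function(lens, rate, bin_size = 1000) {
  bins <- do.call(rbind, lapply(names(lens), function(chr) {
    starts <- seq(0, lens[[chr]] - 1, by = bin_size)
    ends <- pmin(starts + bin_size, lens[[chr]])
    data.frame(chrom = chr, start = starts, end = ends,
               count = rate * (ends - starts), stringsAsFactors = FALSE)
  }))
  depth_track(bins, bin_size, lens)
}

# Multiply selected chromosomes' counts (noiseless disomy).
scale_chroms <- function(track, chroms, factor = 2) {
  b <- track$bins
  b$count[b$chrom %in% chroms] <- b$count[b$chrom %in% chroms] * factor
  depth_track(b, track$bin_size, track$chrom_lengths)
}

# Independent effect-class oracle: rebuild the full mutant CDS, translate
# reference and mutant proteins with Biostrings, and diff them.
oracle_classify <- function(v, genome) {
  genes <- genome$genes
  hit <- which(genes$chrom == v$chrom & genes$start <= v$pos &
                 genes$end >= v$pos)
  if (length(hit) == 0L) return("noncoding")
  g <- genes[hit, ]
  chrom_seq <- as.character(genome$sequences[[g$chrom]])
  stopifnot(substr(chrom_seq, v$pos, v$pos) == v$ref)
  mut_seq <- chrom_seq
  substr(mut_seq, v$pos, v$pos) <- v$alt
  get_prot <- function(s) {
    cds <- Biostrings::DNAString(substr(s, g$start, g$end))
    if (g$strand == "-") cds <- Biostrings::reverseComplement(cds)
    # plain standard code: no alternative-initiator special-casing
    as.character(Biostrings::translate(cds, no.init.codon = TRUE))
  }
  ref_p <- get_prot(chrom_seq)
  alt_p <- get_prot(mut_seq)
  if (ref_p == alt_p) return("silent")
  d <- which(strsplit(ref_p, "")[[1]] != strsplit(alt_p, "")[[1]])[1]
  if (substr(alt_p, d, d) == "*" && substr(ref_p, d, d) != "*") "nonsense"
  else "missense"
}

# Vectorized oracle over a variant table (returns a character vector).
oracle_classify_all <- function(records, genome) {
  vapply(seq_len(nrow(records)), function(i)
    oracle_classify(records[i, ], genome), character(1))
}

# Batch version of the translation oracle: rebuilds every mutant CDS,
# translates reference and mutant proteins in one Biostrings call per set,
# and diffs the protein strings. Assumes single-base substitutions and
# non-overlapping genes.
oracle_classify_batch <- function(records, genome) {
  genes <- genome$genes
  out <- rep("noncoding", nrow(records))
  if (nrow(genes) == 0L) return(out)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  revcomp_str <- function(s)
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  for (j in seq_len(nrow(genes))) {
    gj <- genes[j, ]
    sel <- which(records$chrom == gj$chrom & records$pos >= gj$start &
                   records$pos <= gj$end)
    if (!length(sel)) next
    genomic <- as.character(Biostrings::subseq(genome$sequences[[gj$chrom]],
                                               gj$start, gj$end))
    ref_cds <- if (gj$strand == "+") genomic else revcomp_str(genomic)
    ref_prot <- as.character(Biostrings::translate(
      Biostrings::DNAString(ref_cds), no.init.codon = TRUE))
    mut_cds <- vapply(sel, function(i) {
      off <- if (gj$strand == "+") records$pos[i] - gj$start + 1L else
        gj$end - records$pos[i] + 1L
      base <- if (gj$strand == "+") records$alt[i] else comp[[records$alt[i]]]
      s <- ref_cds
      substr(s, off, off) <- base
      s
    }, character(1))
    mut_prot <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(mut_cds), no.init.codon = TRUE))
    for (m in seq_along(sel)) {
      if (mut_prot[m] == ref_prot) { out[sel[m]] <- "silent"; next }
      rp <- strsplit(ref_prot, "")[[1]]
      mp <- strsplit(mut_prot[m], "")[[1]]
      d <- which(rp != mp)[1]
      out[sel[m]] <- if (mp[d] == "*" && rp[d] != "*") "nonsense" else "missense"
    }
  }
  out
}

# Enumeration oracle for the hypergeometric upper tail: fraction of all
# size-n subsets of 1..N whose overlap with {1..K} is at least k.
enum_tail_p <- function(N, K, n, k) {
  if (n == 0) return(if (k <= 0) 1 else 0)
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

# Noiseless Gaussian line profile.
gaussian_profile <- function(x, A, mu, sigma, c0 = 0, noise_sd = 0) {
  y <- A * exp(-(x - mu)^2 / (2 * sigma^2)) + c0
  if (noise_sd > 0) y <- y + rnorm(length(x), 0, noise_sd)
  structure(data.frame(position = x, intensity = y),
            class = c("line_scan_profile", "data.frame"))
}

# Random non-overlapping disks inside a frame, by rejection.
random_disks <- function(n, size, r_range = c(4, 8), margin = 10) {
  disks <- data.frame(x = numeric(), y = numeric(), r = numeric())
  attempts <- 0
  while (nrow(disks) < n && attempts < 5000) {
    attempts <- attempts + 1
    r <- runif(1, r_range[1], r_range[2])
    x <- runif(1, margin + r, size[1] - margin - r)
    y <- runif(1, margin + r, size[2] - margin - r)
    if (nrow(disks) == 0 ||
        all(sqrt((disks$x - x)^2 + (disks$y - y)^2) > disks$r + r + 3))
      disks <- rbind(disks, data.frame(x = x, y = y, r = r))
  }
  stopifnot(nrow(disks) == n)
  disks
}
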