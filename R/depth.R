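#' Binned read-depth track
#'
#' Per-chromosome binned read counts with 0-based half-open intervals
#' (bedGraph convention). Bins must tile each chromosome without overlap;
#' the last bin of a chromosome may be short.
#'
#' @param bins Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `count` (reads per bin, non-negative).
#' @param bin_size Nominal bin width in bp.
#' @param chrom_lengths Optional named vector of chromosome lengths; by
#'   default the end of the last bin per chromosome.
#' @return An object of class `depth_track`.
#' @export
depth_track <- function(bins, bin_size, chrom_lengths = NULL) {
  bins <- as.data.frame(bins, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "count") %in% names(bins)))
  assert_scalar_number(bin_size, "bin_size", positive = TRUE)
  if (any(bins$count < 0)) stop("bin counts must be non-negative")
  if (any(bins$end <= bins$start)) stop("bins must have end > start")
  bins <- bins[order(bins$chrom, bins$start), , drop = FALSE]
  for (chr in unique(bins$chrom)) {
    b <- bins[bins$chrom == chr, , drop = FALSE]
    if (b$start[1] != 0 || (nrow(b) > 1 && any(b$start[-1] != b$end[-nrow(b)])))
      stop("bins do not tile chromosome ", chr)
  }
  if (is.null(chrom_lengths))
    chrom_lengths <- tapply(bins$end, bins$chrom, max)
  structure(list(bins = bins, bin_size = bin_size,
                 chrom_lengths = chrom_lengths[unique(bins$chrom)],
                 total_reads = sum(bins$count)),
            class = "depth_track")
}

#' @export
print.depth_track <- function(x, ...) {
  cat(sprintf("<depth_track> %d chromosomes, %d bins of %g bp, %s reads\n",
              length(x$chrom_lengths), nrow(x$bins), x$bin_size,
              format(round(x$total_reads), big.mark = ",")))
  invisible(x)
}

#' Ground-truth karyotype for simulation
#'
#' Baseline ploidy is haploid; per-chromosome copy number is 1 or 2
#' (disomy), and segmental events override copy number over a sub-interval.
#'
#' @param copy_number Named integer vector over chromosomes, values in
#'   `{1, 2}`.
#' @param segments Data frame `chrom`, `start`, `end` (0-based half-open),
#'   `copy_number`; may be empty.
#' @param chrom_lengths Named lengths used to bound-check segments
#'   (optional).
#' @return An object of class `karyotype_truth`.
#' @export
karyotype_truth <- function(copy_number,
                            segments = data.frame(chrom = character(),
                                                  start = numeric(),
                                                  end = numeric(),
                                                  copy_number = numeric()),
                            chrom_lengths = NULL) {
  stopifnot(!is.null(names(copy_number)), all(copy_number %in% c(1, 2)))
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  if (nrow(segments) > 0) {
    stopifnot(all(segments$chrom %in% names(copy_number)),
              all(segments$end > segments$start))
    if (!is.null(chrom_lengths) &&
        any(segments$end > chrom_lengths[segments$chrom] | segments$start < 0))
      stop("segmental event outside chromosome bounds")
  }
  structure(list(copy_number = copy_number, segments = segments),
            class = "karyotype_truth")
}

#' Simulation configuration
#'
#' One root seed fully determines all generator output; sub-streams for the
#' depth and variant generators are derived deterministically from it.
#'
#' @param seed Integer root seed.
#' @param coverage Mean per-bin read count at copy number 1 (lambda).
#' @param bin_size Depth bin width in bp (default 1000).
#' @param noise `"poisson"` (default) or `"nb"` (negative binomial) bin
#'   noise; the paper-scale data motivate Poisson, the NB option probes
#'   robustness to overdispersion.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param n_strains Cohort size for pipeline-level simulation.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, coverage = 100, bin_size = 1000,
                       noise = c("poisson", "nb"), nb_dispersion = 0.1,
                       n_strains = 10L) {
  noise <- match.arg(noise)
  assert_scalar_number(coverage, "coverage")
  if (coverage < 0) stop("`coverage` must be >= 0")
  assert_scalar_number(bin_size, "bin_size", positive = TRUE)
  structure(list(seed = as.integer(seed), coverage = coverage,
                 bin_size = bin_size, noise = noise,
                 nb_dispersion = nb_dispersion,
                 n_strains = as.integer(n_strains)),
            class = "sim_config")
}

#' Simulate a binned depth track from a known karyotype
#'
#' Each bin's count is drawn with mean `coverage * copy_number *
#' bin_width / bin_size`, so copy-number-2 regions have doubled expected
#' depth and short terminal bins are scaled by width. A bin overlapping a
#' segmental event takes the event's copy number if its midpoint falls
#' inside the event.
#'
#' @param genome A [genome_model()] (supplies chromosome lengths).
#' @param truth A [karyotype_truth()].
#' @param cfg A [sim_config()].
#' @return A [depth_track()].
#' @export
simulate_depth <- function(genome, truth, cfg) {
  lens <- chrom_lengths(genome)
  stopifnot(all(names(truth$copy_number) %in% names(lens)))
  rows <- lapply(names(truth$copy_number), function(chr) {
    L <- lens[[chr]]
    starts <- seq(0, L - 1, by = cfg$bin_size)
    ends <- pmin(starts + cfg$bin_size, L)
    cn <- rep(truth$copy_number[[chr]], length(starts))
    seg <- truth$segments[truth$segments$chrom == chr, , drop = FALSE]
    if (nrow(seg) > 0) {
      mid <- (starts + ends) / 2
      for (k in seq_len(nrow(seg))) {
        inside <- mid >= seg$start[k] & mid < seg$end[k]
        cn[inside] <- seg$copy_number[k]
      }
    }
    data.frame(chrom = chr, start = starts, end = ends, cn = cn,
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, rows)
  mu <- cfg$coverage * bins$cn * (bins$end - bins$start) / cfg$bin_size
  bins$count <- with_seed(derive_seed(cfg$seed, "depth"), {
    if (cfg$noise == "poisson") rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion)
  })
  bins$cn <- NULL
  depth_track(bins, cfg$bin_size, lens[names(truth$copy_number)])
}

#' Write a depth track as bedGraph
#' @param track A [depth_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  gr <- GenomicRanges::GRanges(
    track$bins$chrom,
    IRanges::IRanges(track$bins$start + 1, track$bins$end),
    score = track$bins$count)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into a depth track
#' @param path bedGraph path (chrom, 0-based half-open interval, count).
#' @param bin_size Nominal bin size; inferred from the most common bin
#'   width when `NULL`.
#' @return A [depth_track()].
#' @export
read_bedgraph <- function(path, bin_size = NULL) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  bins <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = GenomicRanges::end(gr),
    count = gr$score, stringsAsFactors = FALSE)
  if (is.null(bin_size)) {
    w <- bins$end - bins$start
    bin_size <- as.numeric(names(sort(table(w), decreasing = TRUE))[1])
  }
  depth_track(bins, bin_size)
}

#' Re-bin a depth track to a coarser bin size
#'
#' Counts are allocated to new bins in proportion to interval overlap; with
#' a new bin size that is an integer multiple of the old one this is an
#' exact sum.
#'
#' @param track A [depth_track()].
#' @param new_bin_size Target bin width in bp (> 0).
#' @return A [depth_track()] at the new bin size.
#' @export
rebin_track <- function(track, new_bin_size) {
  assert_scalar_number(new_bin_size, "new_bin_size", positive = TRUE)
  rows <- lapply(names(track$chrom_lengths), function(chr) {
    b <- track$bins[track$bins$chrom == chr, , drop = FALSE]
    L <- track$chrom_lengths[[chr]]
    starts <- seq(0, L - 1, by = new_bin_size)
    ends <- pmin(starts + new_bin_size, L)
    counts <- numeric(length(starts))
    idx <- pmin(floor(b$start / new_bin_size) + 1, length(starts))
    for (k in seq_len(nrow(b))) {
      s <- b$start[k]; e <- b$end[k]; cnt <- b$count[k]
      i <- idx[k]
      while (s < e) {
        seg_end <- min(e, ends[i])
        counts[i] <- counts[i] + cnt * (seg_end - s) / (e - b$start[k])
        s <- seg_end
        i <- i + 1
      }
    }
    data.frame(chrom = chr, start = starts, end = ends, count = counts,
               stringsAsFactors = FALSE)
  })
  depth_track(do.call(rbind, rows), new_bin_size, track$chrom_lengths)
}
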