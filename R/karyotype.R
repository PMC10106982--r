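#' Parameters for karyotype calling
#'
#' Houses the constants of the read-depth normalization scheme: only the
#' 15 kb closest to the telomeres enters the per-chromosome depth (to
#' equalize sampling across chromosomes of different lengths), the
#' euploid reference is taken from the second-lowest quartile of
#' per-chromosome depths (robust to inflation by disomic chromosomes), a
#' chromosome with normalized copy number strictly greater than 1.5 is
#' called disomic, and segmental events are sought at 4 kb resolution.
#'
#' @param telomere_window Window length per chromosome end, bp (default
#'   15000). If twice the window reaches the chromosome length, the whole
#'   chromosome is used instead.
#' @param ends Which telomere-proximal windows to use: `"both"` (default,
#'   averaged per bp), `"left"` or `"right"`.
#' @param disomy_threshold Normalized copy number above which (strictly) a
#'   chromosome is called disomic (default 1.5).
#' @param reference_stat Summary over the second-quartile slice: `"mean"`
#'   (default) or `"median"`.
#' @param segment_bin_size Bin width for segmental detection, bp (default
#'   4000).
#' @param segment_ratio_threshold Normalized ratio above which (strictly) a
#'   bin counts toward an amplified run (default 1.5).
#' @param min_segment_bins Minimum consecutive amplified bins per reported
#'   segment (default 5, i.e. 20 kb).
#' @param large_segment_length Minimum length for a partial-chromosome
#'   amplification to flag a strain for exclusion from aneuploidy
#'   summaries (default 100000 bp; a declared choice, the original
#'   criterion being visual).
#' @return An object of class `karyotype_params`.
#' @export
karyotype_params <- function(telomere_window = 15000,
                             ends = c("both", "left", "right"),
                             disomy_threshold = 1.5,
                             reference_stat = c("mean", "median"),
                             segment_bin_size = 4000,
                             segment_ratio_threshold = 1.5,
                             min_segment_bins = 5L,
                             large_segment_length = 100000) {
  ends <- match.arg(ends)
  reference_stat <- match.arg(reference_stat)
  for (nm in c("telomere_window", "disomy_threshold", "segment_bin_size",
               "segment_ratio_threshold", "min_segment_bins",
               "large_segment_length"))
    assert_scalar_number(get(nm), nm, positive = TRUE)
  structure(list(telomere_window = telomere_window, ends = ends,
                 disomy_threshold = disomy_threshold,
                 reference_stat = reference_stat,
                 segment_bin_size = segment_bin_size,
                 segment_ratio_threshold = segment_ratio_threshold,
                 min_segment_bins = as.integer(min_segment_bins),
                 large_segment_length = large_segment_length),
            class = "karyotype_params")
}

# Reads attributed to [w_start, w_end) from bins overlapping the window,
# pro-rated by overlap fraction (bins are assumed locally uniform).
window_reads <- function(bins, w_start, w_end) {
  ov <- pmin(bins$end, w_end) - pmax(bins$start, w_start)
  ov <- pmax(ov, 0)
  sum(bins$count * ov / (bins$end - bins$start))
}

#' Mean telomere-proximal depth of one chromosome
#'
#' Mean per-bp read depth over the telomere-proximal window(s) of a
#' chromosome. With `ends = "both"` the two windows are pooled (total reads
#' over total window length). If twice the window is at least the
#' chromosome length, the whole chromosome is used.
#'
#' @param track A [depth_track()].
#' @param chrom Chromosome name.
#' @param params A [karyotype_params()].
#' @return Depth in reads per bp.
#' @export
telomere_window_depth <- function(track, chrom, params = karyotype_params()) {
  if (!chrom %in% names(track$chrom_lengths))
    stop("unknown chromosome: ", chrom)
  L <- as.numeric(track$chrom_lengths[[chrom]])
  b <- track$bins[track$bins$chrom == chrom, , drop = FALSE]
  w <- params$telomere_window
  if (2 * w >= L)  # windows would overlap: fall back to the whole chromosome
    return(sum(b$count) / L)
  windows <- switch(params$ends,
    both = list(c(0, w), c(L - w, L)),
    left = list(c(0, w)),
    right = list(c(L - w, L)))
  reads <- sum(vapply(windows, function(win) window_reads(b, win[1], win[2]),
                      numeric(1)))
  reads / (w * length(windows))
}

#' Second-lowest-quartile reference depth
#'
#' The euploid baseline: the summary (mean by default) of the
#' per-chromosome depth values whose ascending rank lies in the second
#' quartile, ranks `ceiling(n/4) + 1` through `ceiling(n/2)` (ranks 5–8 of
#' 16). Disomic chromosomes occupy the upper ranks and cannot inflate this
#' reference as long as at most `ceiling(n/4)` chromosomes are affected
#' below and at most half in total.
#'
#' @param per_chrom_values Numeric vector of per-chromosome depths
#'   (reads/bp), length >= 4.
#' @param stat `"mean"` (default) or `"median"` over the quartile slice.
#' @return Reference depth in reads per bp.
#' @export
reference_depth <- function(per_chrom_values, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  n <- length(per_chrom_values)
  if (n < 4L) stop("reference_depth needs at least 4 chromosomes, got ", n)
  if (all(per_chrom_values == 0)) stop("no coverage: all chromosome depths are zero")
  sorted <- sort(per_chrom_values)
  slice <- sorted[(ceiling(n / 4) + 1):ceiling(n / 2)]
  if (stat == "mean") mean(slice) else median(slice)
}

#' Call per-chromosome copy number from binned depth
#'
#' Normalized copy number is the telomere-window depth of each chromosome
#' divided by the second-lowest-quartile reference over all chromosomes; a
#' chromosome is flagged disomic when its normalized copy number strictly
#' exceeds the disomy threshold (a value exactly at the threshold is
#' euploid).
#'
#' @param track A [depth_track()].
#' @param params A [karyotype_params()].
#' @return Data frame (class `chrom_copy_calls`) with columns `chrom`,
#'   `telomere_depth` (reads/bp), `copy_number` (normalized, euploid ~ 1)
#'   and `disomic`.
#' @export
call_karyotype <- function(track, params = karyotype_params()) {
  chroms <- names(track$chrom_lengths)
  depths <- vapply(chroms, function(ch) telomere_window_depth(track, ch, params),
                   numeric(1))
  ref <- reference_depth(depths, params$reference_stat)
  calls <- data.frame(
    chrom = chroms, telomere_depth = as.numeric(depths),
    copy_number = as.numeric(depths) / ref,
    stringsAsFactors = FALSE)
  calls$disomic <- calls$copy_number > params$disomy_threshold
  class(calls) <- c("chrom_copy_calls", class(calls))
  attr(calls, "reference_depth") <- ref
  calls
}

#' Detect segmental amplifications at bin resolution
#'
#' Re-bins the track to the segment bin size (4 kb by default), normalizes
#' each bin's per-bp depth by a genome-wide reference, and reports maximal
#' runs of at least `min_segment_bins` consecutive bins whose ratio
#' strictly exceeds the segment ratio threshold. Whole-chromosome disomies
#' are recovered as chromosome-spanning segments and are distinguished by
#' the `chrom_spanning` column. The run-length rule is an explicit,
#' configurable stand-in for what was originally a visual call.
#'
#' @param track A [depth_track()]; re-binned internally unless its bin size
#'   already equals `params$segment_bin_size`.
#' @param reference Genome-wide reference depth (reads/bp). Default: the
#'   second-lowest-quartile reference over per-chromosome whole-length mean
#'   depths.
#' @param params A [karyotype_params()].
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open, multiples of the segment bin except at chromosome ends),
#'   `n_bins`, `mean_ratio`, `chrom_spanning`, sorted by chromosome and
#'   start.
#' @export
detect_segments <- function(track, reference = NULL,
                            params = karyotype_params()) {
  if (track$bin_size != params$segment_bin_size)
    track <- rebin_track(track, params$segment_bin_size)
  if (is.null(reference)) {
    chrom_means <- vapply(names(track$chrom_lengths), function(ch) {
      b <- track$bins[track$bins$chrom == ch, , drop = FALSE]
      sum(b$count) / as.numeric(track$chrom_lengths[[ch]])
    }, numeric(1))
    reference <- reference_depth(chrom_means, params$reference_stat)
  }
  assert_scalar_number(reference, "reference", positive = TRUE)
  out <- list()
  for (chr in names(track$chrom_lengths)) {
    b <- track$bins[track$bins$chrom == chr, , drop = FALSE]
    ratio <- (b$count / (b$end - b$start)) / reference
    amp <- ratio > params$segment_ratio_threshold
    r <- rle(amp)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1L
    keep <- r$values & r$lengths >= params$min_segment_bins
    for (k in which(keep)) {
      i1 <- starts_idx[k]; i2 <- ends_idx[k]
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = b$start[i1], end = b$end[i2],
        n_bins = i2 - i1 + 1L, mean_ratio = mean(ratio[i1:i2]),
        chrom_spanning = b$start[i1] == 0 &&
          b$end[i2] == as.numeric(track$chrom_lengths[[chr]]),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_bins = integer(),
                      mean_ratio = numeric(), chrom_spanning = logical(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

#' Flag a strain carrying a large partial-chromosome amplification
#'
#' Strains with large segmental amplifications are excluded from cohort
#' aneuploidy summaries; a segment spanning a whole chromosome is a disomy,
#' not a segmental event, and never triggers the flag.
#'
#' @param segments Output of [detect_segments()] for one strain.
#' @param params A [karyotype_params()] (uses `large_segment_length`).
#' @return `TRUE` if any non-spanning segment is at least
#'   `large_segment_length` long.
#' @export
flag_large_segmental <- function(segments, params = karyotype_params()) {
  if (nrow(segments) == 0L) return(FALSE)
  partial <- !segments$chrom_spanning
  any(partial & (segments$end - segments$start) >= params$large_segment_length)
}

#' Write per-strain karyotype calls as TSV
#' @param calls Output of [call_karyotype()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_karyotype_tsv <- function(calls, path) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
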