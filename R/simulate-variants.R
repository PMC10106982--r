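#' Simulate ancestor and evolved variant sets with known effect classes
#'
#' Draws `n_ancestral` substitutions present in both the ancestor and the
#' evolved strain, plus exactly the requested number of novel evolved-only
#' substitutions of each effect class. The evolved set is therefore the
#' ancestor set plus the novel records, and [subtract_ancestor()] recovers
#' exactly the novel ones. Each novel record's true effect class is
#' returned as ground truth, and classifying it with [classify_effect()]
#' reproduces the label. Optionally, extra novel records are drawn with
#' quality or depth deliberately on the failing side of the default
#' filters, to exercise [filter_variants()].
#'
#' @param genome A [genome_model()] with at least one gene if any coding
#'   class is requested.
#' @param n_ancestral Number of shared ancestral variants.
#' @param n_novel_by_class Named counts over
#'   `c("noncoding", "silent", "missense", "nonsense")`; missing names
#'   default to 0.
#' @param cfg A [sim_config()]; its seed (sub-stream `"variants"`)
#'   determines everything.
#' @param n_below_filter Number of additional novel records drawn to fail
#'   the default quality/depth filter (half fail on quality, half on
#'   depth under mode `"max"`).
#' @param qual_range,depth_range Uniform ranges for passing records
#'   (defaults keep qual > 95 and depth <= 300).
#' @return A list (class `variant_sim`) with elements `ancestor`,
#'   `evolved` (variant data frames) and `truth` (novel records with
#'   columns `effect` and `passes_filter`).
#' @export
simulate_variants <- function(genome, n_ancestral = 5L,
                              n_novel_by_class = c(noncoding = 4L, silent = 2L,
                                                   missense = 3L, nonsense = 1L),
                              cfg = sim_config(),
                              n_below_filter = 0L,
                              qual_range = c(96, 200),
                              depth_range = c(50, 300)) {
  classes <- c("noncoding", "silent", "missense", "nonsense")
  counts <- setNames(rep(0L, 4L), classes)
  counts[names(n_novel_by_class)] <- as.integer(n_novel_by_class)
  if (any(!names(n_novel_by_class) %in% classes))
    stop("unknown effect class in `n_novel_by_class`")
  if (sum(counts[c("silent", "missense", "nonsense")]) > 0 &&
      nrow(genome$genes) == 0L)
    stop("coding mutations requested but the genome has no genes")

  with_seed(derive_seed(cfg$seed, "variants"), {
    lens <- chrom_lengths(genome)
    chrom_chars <- lapply(genome$sequences, as.character)
    bases <- c("A", "C", "G", "T")
    used <- character(0)

    draw_candidates <- function(m, coding) {
      # sample m random positions (inside genes if coding, outside if not)
      if (coding) {
        gi <- sample.int(nrow(genome$genes), m, replace = TRUE)
        g <- genome$genes[gi, , drop = FALSE]
        pos <- g$start + floor(runif(m) * (g$end - g$start + 1))
        chrom <- g$chrom
      } else {
        chrom <- sample(names(lens), m, replace = TRUE,
                        prob = lens / sum(lens))
        pos <- floor(runif(m) * lens[chrom]) + 1
      }
      ref <- vapply(seq_len(m), function(i)
        substr(chrom_chars[[chrom[i]]], pos[i], pos[i]), character(1))
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
      variant_records(chrom, pos, ref, alt, qual = NA_real_)
    }

    take_of_class <- function(cls, k) {
      if (k == 0L) return(NULL)
      got <- NULL
      for (round in 1:40) {
        cand <- draw_candidates(max(50L, 10L * k), coding = cls != "noncoding")
        ann <- annotate_variants(cand, genome)
        ann <- ann[ann$effect == cls & !variant_key(ann) %in% used, , drop = FALSE]
        ann <- ann[!duplicated(paste(ann$chrom, ann$pos)), , drop = FALSE]
        if (nrow(ann) > 0L) {
          got <- rbind(got, ann[seq_len(min(k - NROW0(got), nrow(ann))), ,
                                drop = FALSE])
          used <<- c(used, variant_key(got))
        }
        if (NROW0(got) >= k) return(got)
      }
      stop("could not draw ", k, " '", cls, "' mutation(s): no eligible site ",
           "found in this genome")
    }

    ancestor <- {
      cand <- draw_candidates(max(50L, 10L * n_ancestral), coding = FALSE)
      cand2 <- if (nrow(genome$genes) > 0L)
        draw_candidates(max(50L, 10L * n_ancestral), coding = TRUE) else NULL
      all <- rbind(cand, cand2)
      all <- all[!duplicated(paste(all$chrom, all$pos)), , drop = FALSE]
      if (nrow(all) < n_ancestral)
        stop("could not draw ", n_ancestral, " ancestral variants")
      a <- all[sample.int(nrow(all), n_ancestral), , drop = FALSE]
      used <<- c(used, variant_key(a))
      a
    }

    novel <- do.call(rbind, lapply(classes, function(cls)
      take_of_class(cls, counts[[cls]])))
    truth_effect <- if (is.null(novel)) character() else novel$effect
    novel <- if (is.null(novel)) draw_candidates(0L, FALSE) else
      novel[, c("chrom", "pos", "ref", "alt", "qual", "depth"), drop = FALSE]

    fill_qc <- function(v, pass) {
      n <- nrow(v)
      if (n == 0L) return(v)
      v$qual <- round(runif(n, qual_range[1], qual_range[2]), 1)
      v$depth <- round(runif(n, depth_range[1], depth_range[2]))
      if (!pass && n > 0L) {
        fail_on_qual <- seq_len(n) %% 2L == 1L
        v$qual[fail_on_qual] <- round(runif(sum(fail_on_qual), 5, 95), 1)
        v$depth[!fail_on_qual] <- round(runif(sum(!fail_on_qual), 301, 1000))
      }
      v
    }
    ancestor <- fill_qc(ancestor, pass = TRUE)
    novel <- fill_qc(novel, pass = TRUE)
    passes <- rep(TRUE, nrow(novel))

    if (n_below_filter > 0L) {
      extra <- {
        cand <- draw_candidates(max(50L, 10L * n_below_filter), coding = FALSE)
        cand <- cand[!variant_key(cand) %in% used, , drop = FALSE]
        cand <- cand[!duplicated(paste(cand$chrom, cand$pos)), , drop = FALSE]
        cand[seq_len(min(n_below_filter, nrow(cand))), , drop = FALSE]
      }
      used <- c(used, variant_key(extra))
      extra_effect <- annotate_variants(extra, genome)$effect
      extra <- fill_qc(extra, pass = FALSE)
      novel <- rbind(novel, extra)
      truth_effect <- c(truth_effect, extra_effect)
      passes <- c(passes, rep(FALSE, nrow(extra)))
    }

    truth <- novel
    truth$effect <- truth_effect
    truth$passes_filter <- passes
    evolved <- rbind(ancestor, novel)
    structure(list(ancestor = ancestor, evolved = evolved, truth = truth),
              class = "variant_sim")
  })
}

NROW0 <- function(x) if (is.null(x)) 0L else nrow(x)
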