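#' Gene set with a defined universe
#'
#' The CIN-related category against which mutated genes are tested. The
#' universe may be given as a count (e.g. 6002 annotated genes) or as the
#' full vector of gene ids, in which case category and query membership
#' are checked against it.
#'
#' @param genes Character vector of category gene ids.
#' @param universe Either a single count `N` or a character vector of all
#'   gene ids in the universe.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(genes, universe) {
  genes <- unique(as.character(genes))
  if (is.numeric(universe)) {
    n_universe <- as.integer(universe)
    universe_ids <- NULL
  } else {
    universe_ids <- unique(as.character(universe))
    n_universe <- length(universe_ids)
    if (!all(genes %in% universe_ids))
      stop("category gene(s) outside the universe: ",
           paste(head(setdiff(genes, universe_ids), 5), collapse = ", "))
  }
  if (length(genes) > n_universe)
    stop("category larger than the universe")
  structure(list(genes = genes, n_universe = n_universe,
                 universe_ids = universe_ids),
            class = "gene_set")
}

#' Percentage of the gene universe in a category
#'
#' E.g. 874 CIN-related genes out of 6,002 annotated genes. The exact
#' percentage is returned; [format_percent()] renders it at one decimal for
#' display.
#'
#' @param K Category size.
#' @param N Universe size (> 0).
#' @return `100 * K / N`.
#' @export
category_fraction <- function(K, N) {
  if (N <= 0) stop("universe size must be positive")
  if (K < 0 || K > N) stop("need 0 <= K <= N")
  100 * K / N
}

#' Format a percentage at one decimal for display
#'
#' Truncates toward zero at one decimal place (so 14.56\% displays as
#' "14.5\%"), the convention used for reported category fractions.
#'
#' @param pct Percentage value.
#' @return Character scalar like `"14.5%"`.
#' @export
format_percent <- function(pct) {
  sprintf("%.1f%%", trunc(pct * 10) / 10)
}

#' Exact hypergeometric enrichment of a gene category
#'
#' Tests whether mutated genes over-represent a category: with `N` genes in
#' the universe, `K` in the category, and `n` mutated genes of which `k`
#' fall in the category, the upper-tail probability
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` is computed exactly.
#'
#' Counting is mutation-level by default: the same gene mutated in several
#' strains contributes one hit per mutation (so `n` counts mutations, as
#' in "26 out of 98 mutations"), at the cost of mild dependence between
#' draws under the null. `counting = "per_gene"` collapses the query to
#' unique genes first, matching the hypergeometric sampling model exactly.
#'
#' @param mutated_genes Character vector of gene ids carrying mutations,
#'   one entry per mutation.
#' @param geneset A [gene_set()].
#' @param counting `"per_mutation"` (default) or `"per_gene"`.
#' @return List (class `enrichment_result`): `k`, `n`, `K`, `N`,
#'   `fraction_pct` (`100 * k / n`), `p`.
#' @export
cin_enrichment <- function(mutated_genes, geneset,
                           counting = c("per_mutation", "per_gene")) {
  counting <- match.arg(counting)
  q <- as.character(mutated_genes)
  if (counting == "per_gene") q <- unique(q)
  if (!is.null(geneset$universe_ids)) {
    outside <- !q %in% geneset$universe_ids
    if (any(outside)) {
      warning(sum(outside), " mutated gene(s) outside the universe excluded")
      q <- q[!outside]
    }
  }
  n <- length(q)
  k <- sum(q %in% geneset$genes)
  K <- length(geneset$genes)
  N <- geneset$n_universe
  p <- if (n == 0L) 1 else
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(k = k, n = n, K = K, N = N,
                 fraction_pct = if (n > 0) 100 * k / n else NA_real_,
                 p = p),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment> %d / %d mutated genes in category (%s); K = %d, N = %d, p = %.4g\n",
    x$k, x$n, if (is.na(x$fraction_pct)) "-" else format_percent(x$fraction_pct),
    x$K, x$N, x$p))
  invisible(x)
}

#' Per-strain aneuploidy summary
#'
#' @param strain_id Strain identifier.
#' @param disomic_chroms Character vector of chromosomes called disomic.
#' @param excluded Whether the strain carries a large segmental
#'   amplification and is excluded from cohort aneuploidy statistics.
#' @return An object of class `strain_summary`.
#' @export
strain_summary <- function(strain_id, disomic_chroms = character(),
                           excluded = FALSE) {
  structure(list(strain_id = as.character(strain_id),
                 disomic_chroms = unique(as.character(disomic_chroms)),
                 excluded = isTRUE(excluded)),
            class = "strain_summary")
}

#' Cohort aneuploidy statistics
#'
#' Mean number of disomic chromosomes per strain and, per chromosome, the
#' proportion of strains disomic for it — both over non-excluded strains
#' only (strains with large segmental amplifications are left out).
#'
#' @param strains List of [strain_summary()] objects.
#' @param chromosomes Optional chromosome universe for the frequency table
#'   (default: union of observed disomic chromosomes).
#' @return List (class `collection_summary`): `mean_disomies`,
#'   `per_chrom_freq` (named, in `[0, 1]`), `n_strains`, `n_excluded`.
#' @export
summarize_collection <- function(strains, chromosomes = NULL) {
  stopifnot(length(strains) > 0)
  kept <- Filter(function(s) !s$excluded, strains)
  if (length(kept) == 0L) stop("all strains are excluded")
  counts <- vapply(kept, function(s) length(s$disomic_chroms), integer(1))
  chroms <- chromosomes %||%
    sort(unique(unlist(lapply(kept, `[[`, "disomic_chroms"))))
  freq <- vapply(chroms, function(ch)
    mean(vapply(kept, function(s) ch %in% s$disomic_chroms, logical(1))),
    numeric(1))
  structure(list(mean_disomies = mean(counts),
                 per_chrom_freq = setNames(freq, chroms),
                 n_strains = length(kept),
                 n_excluded = length(strains) - length(kept)),
            class = "collection_summary")
}

#' Minichromosome transmission fidelity
#'
#' The number of colonies growing under selection (uracil dropout, i.e.
#' cells that retained the centromeric minichromosome) divided by the
#' number growing on rich medium. Values above 1 are possible by plating
#' noise and are reported unclamped, with a warning.
#'
#' @param colonies_restrictive Colony count on the selective plate.
#' @param colonies_permissive Colony count on the rich (permissive) plate;
#'   must be > 0.
#' @return Ratio in `[0, Inf)`.
#' @export
transmission_fidelity <- function(colonies_restrictive, colonies_permissive) {
  if (colonies_permissive <= 0)
    stop("permissive-plate colony count must be positive")
  ratio <- colonies_restrictive / colonies_permissive
  if (ratio > 1)
    warning("transmission fidelity above 1 (sampling noise); not clamped")
  ratio
}

#' Unpaired two-sample t-test
#'
#' Student's pooled-variance test by default (the common graphing-software
#' default), Welch on request. When both groups have zero variance and
#' equal means the degenerate case is resolved as `t = 0, p = 1`.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param mode `"student"` (default) or `"welch"`.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
unpaired_t <- function(group_a, group_b, mode = c("student", "welch")) {
  mode <- match.arg(mode)
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b))
      return(list(t = 0, df = length(group_a) + length(group_b) - 2, p = 1))
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                df = length(group_a) + length(group_b) - 2, p = 0))
  }
  res <- t.test(group_a, group_b, var.equal = mode == "student")
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Benjamini–Hochberg adjustment helper for batches of enrichment tests
#'
#' @param p Numeric vector of p-values.
#' @return FDR-adjusted p-values.
#' @export
bh_adjust <- function(p) p.adjust(p, method = "BH")

#' Read a gene-category TSV
#'
#' One gene id per line (first column; header optional with column name
#' `gene_id`).
#'
#' @param path TSV path.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("^gene_id\\b", first)
  df <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  as.character(df[[1]])
}
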