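#' Configuration for an end-to-end pipeline run
#'
#' Either simulate a cohort (mode `"simulate"`, the default: a genome,
#' per-strain karyotype truths, depth tracks and variant sets are
#' generated and written alongside the analysis outputs) or analyze
#' existing inputs (mode `"analyze"`: paths to a FASTA/GFF3 genome, a
#' directory of per-strain bedGraph depth tracks, a directory of evolved
#' VCFs, an ancestor VCF and a gene-category TSV).
#'
#' @param output_dir Output directory (created if missing).
#' @param mode `"simulate"` or `"analyze"`.
#' @param seed Root seed for simulation mode.
#' @param sim A [sim_config()] (simulation mode).
#' @param karyotype A [karyotype_params()].
#' @param filters A [filter_params()].
#' @param genome_args List of arguments for [generate_genome()]
#'   (simulation mode).
#' @param max_disomies Per-strain disomy count is drawn uniformly from
#'   `0:max_disomies` (simulation mode, default 6).
#' @param category_fraction_sim Fraction of genes assigned to the
#'   simulated CIN category (simulation mode, default 0.15, mirroring
#'   874/6002).
#' @param fasta,gff3,depth_dir,vcf_dir,ancestor_vcf,category_tsv Paths
#'   (analyze mode).
#' @return An object of class `run_config`.
#' @export
run_config <- function(output_dir, mode = c("simulate", "analyze"),
                       seed = 1L, sim = sim_config(seed = seed),
                       karyotype = karyotype_params(),
                       filters = filter_params(),
                       genome_args = list(n_chrom = 16L,
                                          length_range = c(60e3, 150e3),
                                          gene_density = 0.5),
                       max_disomies = 6L,
                       category_fraction_sim = 0.15,
                       fasta = NULL, gff3 = NULL, depth_dir = NULL,
                       vcf_dir = NULL, ancestor_vcf = NULL,
                       category_tsv = NULL) {
  mode <- match.arg(mode)
  if (mode == "analyze") {
    paths <- c(fasta = fasta, gff3 = gff3, depth_dir = depth_dir,
               ancestor_vcf = ancestor_vcf, category_tsv = category_tsv,
               vcf_dir = vcf_dir)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("missing input path(s): ", paste(missing, collapse = ", "))
  }
  structure(list(output_dir = output_dir, mode = mode, seed = as.integer(seed),
                 sim = sim, karyotype = karyotype, filters = filters,
                 genome_args = genome_args, max_disomies = max_disomies,
                 category_fraction_sim = category_fraction_sim,
                 fasta = fasta, gff3 = gff3, depth_dir = depth_dir,
                 vcf_dir = vcf_dir, ancestor_vcf = ancestor_vcf,
                 category_tsv = category_tsv),
            class = "run_config")
}

#' Cross-check pipeline inputs without mutating them
#'
#' Validates FASTA/GFF3 consistency (gene intervals in bounds, CDS
#' translatable: length divisible by 3, start/stop codons), depth-track
#' tiling, and VCF reference-base agreement with the FASTA. Returns a
#' diagnostics table rather than stopping, so all problems are reported at
#' once.
#'
#' @param genome A [genome_model()], or `NULL` to skip genome checks.
#' @param tracks Named list of [depth_track()]s (may be empty).
#' @param variant_sets Named list of variant data frames (may be empty).
#' @return Data frame with columns `severity` (`"error"`/`"warning"`),
#'   `stage`, `message`; zero rows when everything is consistent.
#' @export
validate_inputs <- function(genome = NULL, tracks = list(),
                            variant_sets = list()) {
  diags <- list()
  note <- function(severity, stage, message)
    diags[[length(diags) + 1L]] <<- data.frame(
      severity = severity, stage = stage, message = message,
      stringsAsFactors = FALSE)
  if (!is.null(genome)) {
    lens <- chrom_lengths(genome)
    g <- genome$genes
    for (i in seq_len(nrow(g))) {
      if (!g$chrom[i] %in% names(lens)) {
        note("error", "genome", sprintf("gene %s on unknown chromosome %s",
                                        g$gene_id[i], g$chrom[i]))
        next
      }
      if (g$start[i] < 1 || g$end[i] > lens[[g$chrom[i]]])
        note("error", "genome",
             sprintf("gene %s extends past chromosome end", g$gene_id[i]))
      else {
        if ((g$end[i] - g$start[i] + 1L) %% 3L != 0L)
          note("error", "genome",
               sprintf("gene %s CDS length not divisible by 3", g$gene_id[i]))
        else {
          cds <- as.character(gene_cds(genome, g$gene_id[i]))
          if (substr(cds, 1, 3) != "ATG" ||
              !substr(cds, nchar(cds) - 2, nchar(cds)) %in% stop_codons)
            note("error", "genome",
                 sprintf("gene %s CDS lacks start and/or stop codon",
                         g$gene_id[i]))
        }
      }
    }
  }
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    ok <- tryCatch({
      depth_track(tr$bins, tr$bin_size, tr$chrom_lengths); TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      note("error", "depth",
           sprintf("track %s: %s", nm, conditionMessage(ok)))
  }
  if (!is.null(genome)) {
    chrom_chars <- lapply(genome$sequences, as.character)
    lens <- chrom_lengths(genome)
    for (nm in names(variant_sets)) {
      v <- variant_sets[[nm]]
      for (i in seq_len(nrow(v))) {
        if (!v$chrom[i] %in% names(lens) || v$pos[i] < 1 ||
            v$pos[i] > lens[[v$chrom[i]]]) {
          note("error", "variants",
               sprintf("%s: %s:%d outside the genome", nm, v$chrom[i], v$pos[i]))
        } else if (substr(chrom_chars[[v$chrom[i]]], v$pos[i], v$pos[i]) !=
                   v$ref[i])
          note("error", "variants",
               sprintf("%s: reference base mismatch at %s:%d", nm,
                       v$chrom[i], v$pos[i]))
      }
    }
  }
  if (!length(diags))
    return(data.frame(severity = character(), stage = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, diags)
}

simulate_strain_truth <- function(genome, seed, max_disomies) {
  lens <- chrom_lengths(genome)
  with_seed(seed, {
    k <- sample(0:max_disomies, 1L)
    cn <- setNames(rep(1L, length(lens)), names(lens))
    if (k > 0) cn[sample(names(lens), k)] <- 2L
    karyotype_truth(cn, chrom_lengths = lens)
  })
}

#' Run the pipeline end to end
#'
#' Simulation mode: generates a genome and a cohort of strains (random
#' disomies, ancestral plus novel variants with a configurable CIN-like
#' category), writes the raw inputs (FASTA, GFF3, bedGraph, VCF) and then
#' analyzes them exactly as analyze mode would: per-strain karyotype
#' calls, segment detection and exclusion flags, variant filtering,
#' ancestor subtraction and effect annotation, cohort aneuploidy summary
#' and category enrichment. All outputs land under `cfg$output_dir`
#' together with a machine-readable JSON report; the same config and seed
#' reproduce identical outputs.
#'
#' @param cfg A [run_config()].
#' @return The run report (list), invisibly; also written as
#'   `report.json`.
#' @export
run_pipeline <- function(cfg) {
  out <- cfg$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (d in c("inputs", "karyotypes", "variants"))
    dir.create(file.path(out, d), showWarnings = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("cinadapt")),
                 mode = cfg$mode, seed = cfg$seed,
                 params = list(karyotype = unclass(cfg$karyotype),
                               filters = unclass(cfg$filters)),
                 warnings = list())

  if (cfg$mode == "simulate") {
    genome <- do.call(generate_genome,
                      c(cfg$genome_args, list(seed = derive_seed(cfg$seed, "genome"))))
    write_genome(genome, file.path(out, "inputs", "genome.fa"),
                 file.path(out, "inputs", "genes.gff3"))
    n_genes <- nrow(genome$genes)
    category <- with_seed(derive_seed(cfg$seed, "category"),
                          sample(genome$genes$gene_id,
                                 round(cfg$category_fraction_sim * n_genes)))
    writeLines(c("gene_id", category), file.path(out, "inputs", "cin_category.tsv"))
    strain_ids <- sprintf("strain%03d", seq_len(cfg$sim$n_strains))
    ancestor_written <- FALSE
    truths <- list()
    for (i in seq_along(strain_ids)) {
      sid <- strain_ids[i]
      truths[[sid]] <- simulate_strain_truth(
        genome, derive_seed(cfg$seed, paste0("truth-", sid)), cfg$max_disomies)
      scfg <- cfg$sim
      scfg$seed <- derive_seed(cfg$seed, paste0("strain-", sid))
      track <- simulate_depth(genome, truths[[sid]], scfg)
      write_bedgraph(track, file.path(out, "inputs", paste0(sid, ".bedGraph")))
      vs <- simulate_variants(genome, cfg = scfg, n_below_filter = 2L)
      if (!ancestor_written) {
        write_vcf(vs$ancestor, file.path(out, "inputs", "ancestor.vcf"))
        ancestor_written <- TRUE
      } else {
        # one shared parent: reuse the first strain's ancestor set
        vs$evolved <- rbind(read_vcf(file.path(out, "inputs", "ancestor.vcf")),
                            vs$truth[, c("chrom", "pos", "ref", "alt",
                                         "qual", "depth")])
      }
      write_vcf(vs$evolved, file.path(out, "inputs", paste0(sid, ".vcf")))
    }
    cfg$fasta <- file.path(out, "inputs", "genome.fa")
    cfg$gff3 <- file.path(out, "inputs", "genes.gff3")
    cfg$depth_dir <- file.path(out, "inputs")
    cfg$vcf_dir <- file.path(out, "inputs")
    cfg$ancestor_vcf <- file.path(out, "inputs", "ancestor.vcf")
    cfg$category_tsv <- file.path(out, "inputs", "cin_category.tsv")
  }

  genome <- read_genome(cfg$fasta, cfg$gff3)
  depth_files <- sort(list.files(cfg$depth_dir, pattern = "\\.bedGraph$",
                                 full.names = TRUE))
  if (!length(depth_files)) stop("pipeline stage 'karyotype': no bedGraph inputs in ",
                                 cfg$depth_dir)
  ancestor <- read_vcf(cfg$ancestor_vcf)
  category <- read_gene_list(cfg$category_tsv)
  geneset <- gene_set(category, universe = genome$genes$gene_id)

  strains <- list()
  mutated_genes <- character()
  variant_counts <- list()
  for (f in depth_files) {
    sid <- sub("\\.bedGraph$", "", basename(f))
    track <- read_bedgraph(f)
    calls <- call_karyotype(track, cfg$karyotype)
    segs <- detect_segments(track, params = cfg$karyotype)
    excluded <- flag_large_segmental(segs, cfg$karyotype)
    write_karyotype_tsv(calls, file.path(out, "karyotypes",
                                         paste0(sid, ".tsv")))
    strains[[sid]] <- strain_summary(sid, calls$chrom[calls$disomic], excluded)

    vcf <- file.path(cfg$vcf_dir, paste0(sid, ".vcf"))
    if (file.exists(vcf)) {
      evolved <- read_vcf(vcf)
      kept <- filter_variants(evolved, cfg$filters)
      novel <- subtract_ancestor(kept, filter_variants(ancestor, cfg$filters))
      ann <- annotate_variants(novel, genome)
      nonsyn <- select_nonsynonymous(ann)
      write.table(ann, file.path(out, "variants", paste0(sid, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      mutated_genes <- c(mutated_genes, nonsyn$gene_id)
      variant_counts[[sid]] <- list(total = nrow(evolved),
                                    pass_filter = nrow(kept),
                                    novel = nrow(novel),
                                    nonsynonymous = nrow(nonsyn))
    }
  }

  summary <- summarize_collection(strains, chromosomes = names(chrom_lengths(genome)))
  enrich <- cin_enrichment(mutated_genes, geneset)
  write.table(
    data.frame(chrom = names(summary$per_chrom_freq),
               aneuploidy_frequency = as.numeric(summary$per_chrom_freq)),
    file.path(out, "cohort_aneuploidy.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  report$n_strains <- summary$n_strains
  report$n_excluded <- summary$n_excluded
  report$mean_disomies_per_strain <- summary$mean_disomies
  report$per_chrom_freq <- as.list(summary$per_chrom_freq)
  report$variant_counts <- variant_counts
  report$enrichment <- list(k = enrich$k, n = enrich$n, K = enrich$K,
                            N = enrich$N, p = enrich$p)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
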