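test_that("genome generation is seed-deterministic down to the written files", {
  g1 <- generate_genome(n_chrom = 3, length_range = c(35e3, 50e3),
                        gene_density = 0.4, seed = 42)
  g2 <- generate_genome(n_chrom = 3, length_range = c(35e3, 50e3),
                        gene_density = 0.4, seed = 42)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_identical(g1$genes, g2$genes)

  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  write_genome(g1, file.path(d1, "g.fa"), file.path(d1, "g.gff3"))
  write_genome(g2, file.path(d2, "g.fa"), file.path(d2, "g.gff3"))
  expect_identical(readLines(file.path(d1, "g.fa")),
                   readLines(file.path(d2, "g.fa")))
  # gff3 differs only in the date comment line
  strip <- function(p) grep("^##date", readLines(p), invert = TRUE, value = TRUE)
  expect_identical(strip(file.path(d1, "g.gff3")),
                   strip(file.path(d2, "g.gff3")))

  g3 <- generate_genome(n_chrom = 3, length_range = c(35e3, 50e3),
                        gene_density = 0.4, seed = 43)
  expect_false(identical(as.character(g1$sequences),
                         as.character(g3$sequences)))
})

test_that("generated genomes satisfy the annotation invariants at several densities", {
  for (dens in c(0, 0.3, 1)) {
    g <- generate_genome(n_chrom = 2, length_range = c(100e3, 100e3),
                         gene_density = dens, seed = 7)
    expect_silent(validate_genome_model(g))
    expected_genes <- round(dens * 100)  # per 100 kb chromosome
    expect_equal(as.vector(table(factor(g$genes$chrom,
                                        levels = names(g$sequences)))),
                 rep(expected_genes, 2))
    if (dens > 0) {
      cds <- gene_cds(g)
      # no internal in-frame stop codons, so nonsense sites are well-defined
      internal <- lapply(as.character(cds), function(s) {
        codons <- substring(s, seq(1, nchar(s) - 3, 3), seq(3, nchar(s) - 1, 3))
        codons[-length(codons)]
      })
      expect_false(any(unlist(internal) %in% c("TAA", "TAG", "TGA")))
    }
  }
  expect_error(generate_genome(n_chrom = 1, length_range = c(2e3, 2e3),
                               gene_density = 5, seed = 1),
               "cannot pack")
})

test_that("genome FASTA/GFF3 round-trips through the readers", {
  g <- generate_genome(n_chrom = 2, length_range = c(30e3, 40e3),
                       gene_density = 0.5, seed = 5)
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_genome(g, fa, gff)
  g2 <- read_genome(fa, gff)
  expect_identical(as.character(g$sequences), as.character(g2$sequences))
  expect_equal(g$genes[order(g$genes$gene_id), ],
               g2$genes[order(g2$genes$gene_id), ],
               ignore_attr = TRUE)
})

test_that("simulated depth has the configured mean and doubles on disomes", {
  g <- generate_genome(n_chrom = 2, length_range = c(100e3, 100e3),
                       gene_density = 0, seed = 1)
  lens <- chrom_lengths(g)
  cfg <- sim_config(seed = 2, coverage = 100, bin_size = 20)
  # ~10,000 bins, all euploid: sample mean within 3 SE of lambda
  tr <- simulate_depth(g, karyotype_truth(setNames(c(1L, 1L), names(lens))), cfg)
  full <- tr$bins[tr$bins$end - tr$bins$start == cfg$bin_size, ]
  se <- sqrt(100 / nrow(full))
  expect_lt(abs(mean(full$count) - 100), 3 * se)

  # one disomic chromosome: mean bin count ~ 2x the euploid mean
  tr2 <- simulate_depth(g, karyotype_truth(setNames(c(1L, 2L), names(lens))), cfg)
  m <- tapply(tr2$bins$count, tr2$bins$chrom, mean)
  expect_gt(m[[2]] / m[[1]], 1.9)
  expect_lt(m[[2]] / m[[1]], 2.1)

  # zero coverage gives an all-zero track
  tr0 <- simulate_depth(g, karyotype_truth(setNames(c(1L, 1L), names(lens))),
                        sim_config(seed = 3, coverage = 0))
  expect_true(all(tr0$bins$count == 0))

  # determinism
  expect_identical(simulate_depth(g, karyotype_truth(setNames(c(1L, 2L),
                                                              names(lens))), cfg)$bins,
                   tr2$bins)
})

test_that("depth linearity: higher copy number means higher empirical mean", {
  g <- generate_genome(n_chrom = 2, length_range = c(50e3, 50e3),
                       gene_density = 0, seed = 9)
  lens <- chrom_lengths(g)
  fails <- 0L
  for (s in 1:50) {
    cfg <- sim_config(seed = s, coverage = 20)
    tr <- simulate_depth(g, karyotype_truth(setNames(c(1L, 2L), names(lens))), cfg)
    m <- tapply(tr$bins$count, tr$bins$chrom, mean)
    if (m[[2]] <= m[[1]]) fails <- fails + 1L
  }
  expect_lte(fails, 1L)  # <= 2% failure over 50 seeds
})

test_that("simulated variants carry correct ground truth and determinism", {
  g <- generate_genome(n_chrom = 3, length_range = c(40e3, 60e3),
                       gene_density = 0.5, seed = 11)
  req <- c(missense = 3L, silent = 2L, nonsense = 1L, noncoding = 4L)
  cfg <- sim_config(seed = 13)
  vs <- simulate_variants(g, n_ancestral = 5, n_novel_by_class = req,
                          cfg = cfg, n_below_filter = 4)
  # evolved = ancestor + novel; subtraction recovers exactly the novel set
  expect_equal(nrow(vs$evolved), nrow(vs$ancestor) + nrow(vs$truth))
  novel <- subtract_ancestor(vs$evolved, vs$ancestor)
  expect_equal(nrow(novel), nrow(vs$truth))
  # requested class counts among filter-passing records
  passing <- vs$truth[vs$truth$passes_filter, ]
  expect_equal(as.list(table(passing$effect))[names(req)],
               as.list(as.integer(req)), ignore_attr = TRUE)
  # every ground-truth label round-trips through the classifier
  ann <- annotate_variants(vs$truth[, c("chrom", "pos", "ref", "alt",
                                        "qual", "depth")], g)
  expect_identical(ann$effect, vs$truth$effect)
  # deliberately-failing records do fail the default filter
  kept <- filter_variants(vs$truth[, c("chrom", "pos", "ref", "alt",
                                       "qual", "depth")])
  expect_equal(nrow(kept), sum(vs$truth$passes_filter))
  # same seed, same lists
  vs2 <- simulate_variants(g, n_ancestral = 5, n_novel_by_class = req,
                           cfg = cfg, n_below_filter = 4)
  expect_identical(vs$evolved, vs2$evolved)
})

test_that("zero requested novel mutations leaves evolved equal to ancestor", {
  g <- generate_genome(n_chrom = 2, length_range = c(30e3, 30e3),
                       gene_density = 0.3, seed = 3)
  vs <- simulate_variants(g, n_ancestral = 4,
                          n_novel_by_class = c(noncoding = 0L),
                          cfg = sim_config(seed = 8))
  expect_identical(vs$evolved[, c("chrom", "pos", "ref", "alt")],
                   vs$ancestor[, c("chrom", "pos", "ref", "alt")])
  expect_equal(nrow(vs$truth), 0L)
})

test_that("nonsense requests fail loudly when no eligible codon exists", {
  # all-Lys body (AAA/AAG only reach stop via one path each; a gene-free
  # genome is the clean impossible case)
  g <- generate_genome(n_chrom = 1, length_range = c(30e3, 30e3),
                       gene_density = 0, seed = 2)
  expect_error(simulate_variants(g, 0, c(nonsense = 1L), sim_config(seed = 1)),
               "no genes")
})

test_that("synthetic spindle images match their analytic description", {
  spots <- data.frame(x = 40, y = 60, amplitude = 100, sigma = 2)
  img <- synthesize_spindle_image(spots, background = 50, noise_sd = 0,
                                  size = c(100, 120), seed = 1)
  expect_equal(dim(img), c(120, 100))
  expect_equal(img[60, 40], 150)           # center = background + amplitude
  expect_equal(attr(img, "truth")$integrated_intensity, 2 * pi * 100 * 4)

  flat <- synthesize_spindle_image(background = 77, size = c(32, 32))
  expect_true(all(flat == 77))

  # two spots 20 px apart give two local maxima at the stated coordinates
  two <- synthesize_spindle_image(
    data.frame(x = c(30, 50), y = c(40, 40), amplitude = 100, sigma = 2),
    background = 10, noise_sd = 0, size = c(80, 80))
  row40 <- two[40, ]
  local_max <- which(diff(sign(diff(row40))) == -2) + 1L
  expect_setequal(local_max, c(30, 50))

  # determinism under noise
  a <- synthesize_spindle_image(spots, 50, noise_sd = 5, size = c(64, 64), seed = 9)
  b <- synthesize_spindle_image(spots, 50, noise_sd = 5, size = c(64, 64), seed = 9)
  expect_identical(a, b)
})

test_that("synthetic plate images record disk count and covered area", {
  disks <- data.frame(x = c(30, 70, 50), y = c(30, 30, 80), r = 6)
  img <- synthesize_plate_image(disks, foreground = 200, background = 20,
                                size = c(100, 100))
  truth <- attr(img, "truth")
  expect_equal(truth$n_disks, 3)
  expect_equal(truth$area_fraction, mean(img == 200), tolerance = 1e-12)

  empty <- synthesize_plate_image(size = c(50, 50))
  expect_equal(attr(empty, "truth")$n_disks, 0)
  expect_true(all(empty == 20))
})

test_that("16-bit TIFF image round-trip preserves intensities", {
  img <- synthesize_spindle_image(data.frame(x = 10, y = 12, amplitude = 5000,
                                             sigma = 2),
                                  background = 1000, size = c(24, 24))
  p <- tempfile(fileext = ".tif")
  write_image_tiff(img, p)
  back <- read_image(p)
  expect_equal(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1)  # 16-bit quantization only
})
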