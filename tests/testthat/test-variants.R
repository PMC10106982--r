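test_that("quality/depth filtering applies strict thresholds and both depth modes", {
  v <- variant_records(chrom = rep("chrA", 5), pos = 1:5,
                       ref = c("A", "C", "G", "T", "A"),
                       alt = c("G", "T", "A", "C", "T"),
                       qual = c(96, 95, 99, 200, 94),
                       depth = c(150, 150, 301, 300, 100))
  kept <- filter_variants(v)
  # qual 96/depth 150 retained; qual 95 removed (strict); depth 301 removed
  # in mode "max"; depth 300 exactly at the cutoff retained
  expect_equal(kept$pos, c(1L, 4L))

  kept_min <- filter_variants(v, filter_params(depth_mode = "min"))
  expect_equal(kept_min$pos, c(3L, 4L))

  # order preservation
  shuffled <- v[c(4, 1, 3, 2, 5), ]
  expect_equal(filter_variants(shuffled)$pos, c(4L, 1L))
})

test_that("missing depth follows the fail-closed policy", {
  v <- variant_records("chrA", 1:2, c("A", "C"), c("G", "T"),
                       qual = c(100, 100), depth = c(NA, 150))
  expect_message(kept <- filter_variants(v), "without depth dropped")
  expect_equal(kept$pos, 2L)
  kept_pass <- suppressMessages(
    filter_variants(v, filter_params(missing_depth = "pass")))
  expect_equal(kept_pass$pos, c(1L, 2L))
})

test_that("filter monotonicity: tightening thresholds never adds records", {
  set.seed(41)
  v <- variant_records("chrA", 1:200, sample(c("A", "C", "G", "T"), 200, TRUE),
                       "N", qual = runif(200, 50, 150),
                       depth = round(runif(200, 50, 600)))
  v$alt <- ifelse(v$ref == "A", "G", "A")
  key <- cinadapt:::variant_key
  base_keys <- key(filter_variants(v))
  for (q in c(100, 120)) for (d in c(250, 150)) {
    tighter <- filter_variants(v, filter_params(min_qual = q, depth_cutoff = d))
    expect_true(all(key(tighter) %in% base_keys))
  }
})

test_that("ancestor subtraction is a stable-order set difference on (chrom,pos,alt)", {
  mk <- function(pos, alt = "G") variant_records("chrA", pos, "A", alt,
                                                 qual = 100, depth = 100)
  evolved <- mk(c(10, 20, 30))
  ancestor <- mk(20)
  expect_equal(subtract_ancestor(evolved, ancestor)$pos, c(10L, 30L))
  # ancestor empty -> identity; evolved subset of ancestor -> empty
  expect_identical(subtract_ancestor(evolved, evolved[0, ]), evolved)
  expect_equal(nrow(subtract_ancestor(evolved, mk(c(10, 20, 30, 40)))), 0L)
  # the key includes alt: same site, different alt is a novel mutation
  expect_equal(subtract_ancestor(mk(10, "G"), mk(10, "T"))$pos, 10L)
})

test_that("subtraction algebra holds on randomized variant sets", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    pool <- variant_records("chrA", sample(1e4, n), "A", "G",
                            qual = runif(n, 90, 150),
                            depth = round(runif(n, 100, 400)))
    x <- pool[sample(n, sample(n, 1)), ]
    a <- pool[sample(n, sample(n, 1)), ]
    key <- cinadapt:::variant_key
    res <- subtract_ancestor(x, a)
    expect_identical(subtract_ancestor(x, x[0, ]), x)
    expect_equal(nrow(subtract_ancestor(x, x)), 0L)
    expect_true(all(key(res) %in% key(x)))
    expect_false(any(key(res) %in% key(a)))
  }
})

test_that("effect classification handles both strands on the hand-built genome", {
  g <- toy_genome()
  # intergenic
  expect_equal(classify_effect(list(chrom = "chrA", pos = 5, ref = "C",
                                    alt = "T"), g)$effect, "noncoding")
  # G1 (+): ATG AAA TAA. Codon 2 AAA -> GAA: Lys -> Glu, missense
  v <- classify_effect(list(chrom = "chrA", pos = 14, ref = "A", alt = "G"), g)
  expect_equal(v$effect, "missense")
  expect_equal(v$gene_id, "G1")
  expect_equal(v$codon_index, 2L)
  expect_equal(v$aa_change, "K2E")
  # AAA -> TAA: nonsense, reported with the X stop notation
  vn <- classify_effect(list(chrom = "chrA", pos = 14, ref = "A", alt = "T"), g)
  expect_equal(vn$effect, "nonsense")
  expect_equal(vn$aa_change, "K2X")
  # third codon position AAA -> AAG: silent
  vs <- classify_effect(list(chrom = "chrA", pos = 16, ref = "A", alt = "G"), g)
  expect_equal(vs$effect, "silent")

  # G2 (-): CDS ATG CCC TGA; genomic TCAGGGCAT at 31..39.
  # Genomic position 35 is CDS codon 2 middle base (C on the coding strand);
  # G -> T genomic is C -> A on the coding strand: CCC -> CAC, Pro -> His
  vm <- classify_effect(list(chrom = "chrA", pos = 35, ref = "G", alt = "T"), g)
  expect_equal(vm$effect, "missense")
  expect_equal(vm$gene_id, "G2")
  expect_equal(vm$aa_change, "P2H")
  # stop-loss is classified as missense (no readthrough class)
  vl <- classify_effect(list(chrom = "chrA", pos = 31, ref = "T", alt = "C"), g)
  expect_equal(vl$codon_index, 3L)
  expect_equal(vl$effect, "missense")
})

test_that("classification agrees with the full-CDS translation oracle everywhere", {
  g <- toy_genome()
  cases <- do.call(rbind, lapply(1:60, function(pos) {
    ref <- substr(as.character(g$sequences[[1]]), pos, pos)
    data.frame(chrom = "chrA", pos = pos, ref = ref,
               alt = setdiff(c("A", "C", "G", "T"), ref),
               stringsAsFactors = FALSE)
  }))
  cases$qual <- 100; cases$depth <- 100
  ann <- annotate_variants(cases, g)
  expect_identical(ann$effect, oracle_classify_all(cases, g))
})

test_that("strand symmetry: a mirrored gene yields identical effect classes", {
  # same CDS once on + and once on - strand of an otherwise identical locus
  cds <- "ATGGATTGCAAATAA"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
  pad <- strrep("C", 10)
  g_plus <- genome_model(c(chr = paste0(pad, cds, pad)),
                         data.frame(gene_id = "G", chrom = "chr", start = 11,
                                    end = 10 + nchar(cds), strand = "+"))
  g_minus <- genome_model(c(chr = paste0(pad, rc, pad)),
                          data.frame(gene_id = "G", chrom = "chr", start = 11,
                                     end = 10 + nchar(cds), strand = "-"))
  L <- nchar(cds)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (off in seq_len(L)) {
    pos_p <- 10 + off
    pos_m <- 10 + L - off + 1  # mirrored genomic position
    ref_p <- substr(cds, off, off)
    for (alt_p in setdiff(c("A", "C", "G", "T"), ref_p)) {
      e_plus <- classify_effect(list(chrom = "chr", pos = pos_p,
                                     ref = ref_p, alt = alt_p), g_plus)$effect
      e_minus <- classify_effect(list(chrom = "chr", pos = pos_m,
                                      ref = comp[[ref_p]],
                                      alt = comp[[alt_p]]), g_minus)$effect
      expect_identical(e_minus, e_plus)
    }
  }
})

test_that("annotation validates the stated reference base against the genome", {
  g <- toy_genome()
  expect_error(annotate_variants(variant_records("chrA", 14, "C", "G",
                                                 100, 100), g),
               "reference base disagrees")
  expect_error(annotate_variants(variant_records("chrA", 9999, "A", "G",
                                                 100, 100), g),
               "outside chromosome bounds")
})

test_that("nonsynonymous selection keeps missense and nonsense, idempotently", {
  g <- toy_genome()
  cases <- variant_records("chrA", c(5, 14, 14, 16), c("C", "A", "A", "A"),
                           c("T", "G", "T", "G"), qual = 100, depth = 100)
  ann <- annotate_variants(cases, g)
  expect_setequal(ann$effect, c("noncoding", "missense", "nonsense", "silent"))
  sel <- select_nonsynonymous(ann)
  expect_setequal(sel$effect, c("missense", "nonsense"))
  expect_identical(select_nonsynonymous(sel), sel)
  expect_equal(nrow(select_nonsynonymous(ann[ann$effect == "silent", ])), 0L)
})

test_that("minimal VCF round-trips and rejects indels with a warning", {
  v <- variant_records(c("chrA", "chrA", "chrB"), c(100L, 205L, 44L),
                       c("A", "C", "G"), c("G", "T", "A"),
                       qual = c(97.5, 40, 120), depth = c(150, 400, NA))
  p <- tempfile(fileext = ".vcf")
  write_vcf(v, p)
  back <- read_vcf(p)
  expect_equal(back[, c("chrom", "pos", "ref", "alt", "qual")],
               v[, c("chrom", "pos", "ref", "alt", "qual")],
               ignore_attr = TRUE)
  expect_equal(back$depth, c(150, 400, NA))

  lines <- readLines(p)
  lines <- append(lines, "chrA\t300\t.\tAT\tA\t99\tPASS\tDP=100")
  p2 <- tempfile(fileext = ".vcf")
  writeLines(lines, p2)
  expect_warning(back2 <- read_vcf(p2), "non-SNV")
  expect_equal(nrow(back2), 3L)
})
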