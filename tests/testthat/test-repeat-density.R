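test_that("RepeatMasker .out parsing: strand C, exclusions, hand count", {
  f <- withr::local_tempfile(fileext = ".out")
  writeLines(rm_out_fixture(), f)
  ann <- read_repeatmasker(f, dialect = "out")
  # DNA? (low confidence) and Simple_repeat excluded: 2 of 4 instances remain
  expect_equal(length(ann), 2L)
  expect_setequal(ann$family, c("SINE/Alu", "LINE/L1"))
  l1 <- ann[ann$family == "LINE/L1"]
  expect_equal(as.character(GenomicRanges::strand(l1)), "-")  # C -> minus
  alu <- ann[ann$family == "SINE/Alu"]
  expect_equal(GenomicRanges::start(alu), 1001L)
  expect_equal(GenomicRanges::end(alu), 1300L)
})

test_that("rmsk TSV parsing converts UCSC 0-based starts and excludes families", {
  df <- data.frame(
    genoName = "chr1", genoStart = c(1000L, 5000L, 7000L),
    genoEnd = c(1300L, 5200L, 7100L), strand = c("+", "-", "+"),
    repName = c("AluY", "L1M5", "MER5"),
    repClass = c("SINE", "LINE", "DNA?"),
    repFamily = c("Alu", "L1", "MER5"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- read_repeatmasker(f, dialect = "rmsk")
  expect_equal(length(ann), 2L)
  expect_equal(GenomicRanges::start(ann[ann$family == "SINE/Alu"]), 1001L)
  expect_equal(GenomicRanges::end(ann[ann$family == "SINE/Alu"]), 1300L)
  # class-only granularity
  annc <- read_repeatmasker(f, dialect = "rmsk", family_level = "class")
  expect_setequal(annc$family, c("SINE", "LINE"))
})

.mk_ann <- function(start, end, strand, family = "SINE/Alu", chrom = "chr1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                               strand = strand)
  gr$family <- family
  gr$name <- paste0("r", seq_along(gr))
  gr
}

test_that("family_overlap_bp merges nested/overlapping instances", {
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100), "+")
  ann <- .mk_ann(c(1, 41), c(60, 100), "+")
  # overlapping instances cover 100 bases, not 120
  expect_equal(family_overlap_bp(region, "SINE/Alu", "sense", "+", ann), 100L)
  # nothing on the antisense strand
  expect_equal(family_overlap_bp(region, "SINE/Alu", "antisense", "+", ann), 0L)
  # no instances of another family
  expect_equal(family_overlap_bp(region, "LINE/L1", "sense", "+", ann), 0L)
  # full coverage equals region length
  ann2 <- .mk_ann(1, 100, "+")
  expect_equal(family_overlap_bp(region, "SINE/Alu", "sense", "+", ann2), 100L)
})

test_that("density_table: planted 50% intron tiling and zero-repeat genes", {
  spans <- data.frame(gene_id = "g1", chrom = "chr1", start = 1, end = 1000,
                      strand = "+")
  gm <- GeneModels(data.frame(gene_id = "g1", chrom = "chr1",
                              start = c(1, 901), end = c(100, 1000),
                              strand = "+"), spans = spans)
  # intron is [101, 900] (800 bp); tile 400 bp with sense Alu
  ann <- .mk_ann(c(101, 501), c(300, 700), "+")
  dt <- density_table(gm, ann)
  rec <- dt[dt$region == "intron" & dt$orientation == "sense", ]
  expect_equal(rec$density, 0.5)
  expect_equal(rec$region_length, 800L)
  rec_a <- dt[dt$region == "intron" & dt$orientation == "antisense", ]
  expect_equal(rec_a$density, 0)

  # gene with no repeats on its chromosome: all densities zero
  gm2 <- make_gm(gene_id = "g2", chrom = "chr9", start = c(1, 500),
                 end = c(100, 600), strand = "+")
  dt2 <- density_table(gm2, ann)
  expect_true(all(dt2$density == 0))
  # single-exon genes emit no intron records
  gm3 <- make_gm(gene_id = "g3", chrom = "chr1", start = 1, end = 100,
                 strand = "+")
  expect_false("intron" %in% density_table(gm3, ann)$region)
})

test_that("flipping every repeat strand swaps sense and antisense exactly", {
  spec <- genome_spec(
    n_genes = 60,
    repeats = data.frame(family = "SINE/Alu", group = "all",
                         region = "intron",
                         orientation = c("sense", "antisense"),
                         density = c(0.3, 0.1)))
  sim <- simulate_genome(spec, seed = 5)
  flipped <- sim$repeats
  str <- as.character(GenomicRanges::strand(flipped))
  GenomicRanges::strand(flipped) <- ifelse(str == "+", "-", "+")
  a <- density_table(sim$gm, sim$repeats)
  b <- density_table(sim$gm, flipped)
  key <- function(d) d[order(d$gene_id, d$family, d$region, d$orientation), ]
  a <- key(a); b <- key(b)
  swap <- b
  swap$orientation <- ifelse(b$orientation == "sense", "antisense", "sense")
  swap <- key(swap)
  expect_equal(a$density, swap$density)
  expect_true(all(a$density >= 0 & a$density <= 1))
})

test_that("densities agree with a per-base overlap oracle", {
  set.seed(11)
  spec <- genome_spec(
    n_genes = 30,
    repeats = data.frame(family = "SINE/Alu", group = "all",
                         region = c("intron", "exon"),
                         orientation = "sense", density = c(0.4, 0.2)))
  sim <- simulate_genome(spec, seed = 8)
  dt <- density_table(sim$gm, sim$repeats)
  in_reg <- intronic_region(sim$gm)
  for (gid in sample(gene_ids(sim$gm), 10L)) {
    reg <- in_reg[[gid]]
    if (length(reg) == 0L) next
    gs <- as.character(GenomicRanges::strand(sim$gm$genes[gid]))
    chrom <- as.character(GenomicRanges::seqnames(sim$gm$genes[gid]))
    inst <- sim$repeats[sim$repeats$family == "SINE/Alu" &
      as.character(GenomicRanges::strand(sim$repeats)) == gs &
      as.character(GenomicRanges::seqnames(sim$repeats)) == chrom]
    expected <- overlap_oracle(GenomicRanges::start(reg),
                               GenomicRanges::end(reg),
                               GenomicRanges::start(inst),
                               GenomicRanges::end(inst))
    got <- dt$overlap_bp[dt$gene_id == gid & dt$region == "intron" &
                           dt$orientation == "sense"]
    expect_equal(got, expected)
  }
})
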