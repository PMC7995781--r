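test_that("generators are deterministic under a fixed seed", {
  spec <- genome_spec(n_genes = 40)
  s1 <- simulate_genome(spec, seed = 9, sequence = TRUE)
  s2 <- simulate_genome(spec, seed = 9, sequence = TRUE)
  expect_identical(architecture(s1$gm), architecture(s2$gm))
  expect_identical(as.data.frame(s1$repeats), as.data.frame(s2$repeats))
  expect_identical(as.character(s1$sequences), as.character(s2$sequences))
  s3 <- simulate_genome(spec, seed = 10)
  expect_false(identical(architecture(s1$gm), architecture(s3$gm)))

  e1 <- simulate_expression(expression_spec(n_genes = 50), seed = 2)
  e2 <- simulate_expression(expression_spec(n_genes = 50), seed = 2)
  expect_identical(e1$matrix, e2$matrix)

  # written fixture files are byte-identical on rerun
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_genome_files(s1, d1)
  write_genome_files(s2, d2)
  expect_identical(readLines(file.path(d1, "genes.gtf")),
                   readLines(file.path(d2, "genes.gtf")))
  expect_identical(readLines(file.path(d1, "repeats.tsv")),
                   readLines(file.path(d2, "repeats.tsv")))
})

test_that("planted group densities are realised within 10% of target", {
  spec <- genome_spec(
    n_genes = 150,
    repeats = data.frame(family = "SINE/Alu", group = "all",
                         region = "intron", orientation = "sense",
                         density = 0.4))
  sim <- simulate_genome(spec, seed = 21)
  dt <- density_table(sim$gm, sim$repeats)
  realized <- mean(dt$density[dt$region == "intron" &
                                dt$orientation == "sense"])
  expect_gte(realized, 0.36)
  expect_lte(realized, 0.44)
})

test_that("zero-density families emit no instances; density cap enforced", {
  spec <- genome_spec(
    n_genes = 20,
    repeats = data.frame(family = c("SINE/Alu", "LINE/L1"), group = "all",
                         region = "intron", orientation = "sense",
                         density = c(0.2, 0)))
  sim <- simulate_genome(spec, seed = 3)
  expect_false("LINE/L1" %in% sim$repeats$family)
  expect_error(genome_spec(repeats = data.frame(
    family = "SINE/Alu", group = "all", region = "intron",
    orientation = "sense", density = 0.95)), "unattainable")
})

test_that("generated length distributions match the configured medians within 10%", {
  spec <- genome_spec(n_genes = 500,
                      exon_meanlog = log(200), exon_sdlog = 0.5,
                      intron_meanlog = log(2000), intron_sdlog = 0.8,
                      repeats = NULL)
  sim <- simulate_genome(spec, seed = 13)
  ex_w <- unlist(lapply(sim$gm$exons, GenomicRanges::width))
  expect_lt(abs(median(ex_w) - 200) / 200, 0.1)
  intr_w <- GenomicRanges::width(unlist(intronic_region(sim$gm)))
  expect_lt(abs(median(intr_w) - 2000) / 2000, 0.1)
})

test_that("round-tripped files reproduce the in-memory genome", {
  spec <- genome_spec(
    n_genes = 30,
    repeats = data.frame(family = "SINE/Alu", group = "all",
                         region = "intron", orientation = "sense",
                         density = 0.3))
  sim <- simulate_genome(spec, seed = 6, sequence = TRUE)
  d <- withr::local_tempdir()
  paths <- write_genome_files(sim, d)
  gm2 <- read_gene_models(paths[["gtf"]])
  expect_equal(architecture(gm2), architecture(sim$gm))
  ann2 <- read_repeatmasker(paths[["rmsk"]], dialect = "rmsk")
  expect_equal(GenomicRanges::start(ann2), GenomicRanges::start(sim$repeats))
  expect_equal(ann2$family, sim$repeats$family)
  seqs <- Biostrings::readDNAStringSet(paths[["fasta"]])
  expect_equal(as.character(seqs), as.character(sim$sequences))
})

test_that("planted motifs are found where planted and attributed to their family", {
  spec <- genome_spec(
    n_genes = 40,
    repeats = data.frame(family = "SINE/Alu", group = "all",
                         region = "intron", orientation = "sense",
                         density = 0.3))
  sim <- simulate_genome(spec, seed = 17, sequence = TRUE)
  mot <- simulate_motifs(sim, n_motifs = 20, family_fraction = c("SINE/Alu" = 0.4),
                         unplaced_fraction = 0.1, seed = 18)
  hits <- find_motif_hits(mot$motifs, mot$genome$sequences)
  em <- exonic_motif_table(hits, sim$gm)

  planted_exonic <- mot$truth[!is.na(mot$truth$exon_gene), ]
  for (i in seq_len(nrow(planted_exonic))) {
    expect_true(any(em$gene_id == planted_exonic$exon_gene[i] &
                      em$motif_id == planted_exonic$motif_id[i]))
  }
  att <- attribute_to_families(hits, sim$repeats,
                               motif_ids = mot$motifs$motif_id)
  planted_fam <- mot$truth[!is.na(mot$truth$family), ]
  for (i in seq_len(nrow(planted_fam))) {
    expect_true(planted_fam$family[i] %in%
                  att$per_motif[[planted_fam$motif_id[i]]])
  }
  # motifs left unplaced have no hits (12+ bp random motifs never occur by
  # chance in a genome this small)
  unplaced <- mot$truth$motif_id[is.na(mot$truth$exon_gene)]
  expect_false(any(hits$motif_id %in% unplaced))
})

test_that("planted expression markers are recovered by the permutation test", {
  es <- expression_spec(n_genes = 300, tissues = c("A", "B"),
                        samples_per_tissue = 6, markers_per_tissue = 15,
                        marker_fold = 4, noise_sdlog = 0.3)
  se <- simulate_expression(es, seed = 31)
  a_ids <- names(se$labels)[se$labels == "A"]
  b_ids <- names(se$labels)[se$labels == "B"]
  # log scale equalises per-gene variances across the abundance range
  de <- permutation_de(log2(se$matrix + 1), a_ids, b_ids, n_perm = 1000,
                       fdr_threshold = 0.05, seed = 32)
  b_markers <- se$truth$gene_id[se$truth$role == "marker" &
                                  se$truth$tissue == "B"]
  a_markers <- se$truth$gene_id[se$truth$role == "marker" &
                                  se$truth$tissue == "A"]
  expect_gte(mean(b_markers %in% de$up), 0.8)
  expect_gte(mean(a_markers %in% de$down), 0.8)

  # permuting the labels destroys the planted signal
  set.seed(33)
  shuffled <- sample(colnames(se$matrix))
  de0 <- permutation_de(log2(se$matrix + 1), shuffled[1:6], shuffled[7:12],
                        n_perm = 1000, seed = 34)
  expect_lte(length(de0$up) + length(de0$down),
             length(b_markers) + length(a_markers))
})
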