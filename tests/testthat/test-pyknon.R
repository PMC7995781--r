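test_that("motif search finds overlapping occurrences and matches a naive oracle", {
  h <- find_motif_hits(data.frame(motif_id = "m1", sequence = "AAA"),
                       c(s = "AAAA"))
  expect_equal(h$start, c(1L, 2L))
  h2 <- find_motif_hits(data.frame(motif_id = "m1", sequence = "ACGT"),
                        c(s = "ACGTACGT"))
  expect_equal(h2$start, c(1L, 5L))
  expect_equal(nrow(find_motif_hits(
    data.frame(motif_id = "m1", sequence = "GGGGGG"), c(s = "ACacGT"))), 0L)
  # N never matches
  hN <- find_motif_hits(data.frame(motif_id = "m1", sequence = "ACG"),
                        c(s = "ANGACG"))
  expect_equal(hN$start, 4L)
  expect_error(find_motif_hits(
    data.frame(motif_id = "m1", sequence = "ACGTN"), c(s = "ACGT")),
    "non-ACGT")

  set.seed(6)
  seqs <- c(c1 = random_seq(3000), c2 = random_seq(2000))
  motifs <- data.frame(
    motif_id = sprintf("m%02d", 1:20),
    sequence = vapply(sample(3:6, 20, TRUE),
                      function(L) random_seq(L), ""))
  hits <- find_motif_hits(motifs, seqs)
  for (i in seq_len(nrow(motifs))) {
    for (cn in names(seqs)) {
      got <- sort(hits$start[hits$motif_id == motifs$motif_id[i] &
                               hits$seqname == cn])
      expect_equal(got, sort(naive_motif_hits(motifs$sequence[i], seqs[[cn]])))
    }
  }
})

test_that("reverse-complement matches are reported only with both_strands", {
  seqs <- c(s = "AAAGATCTTT")
  m <- data.frame(motif_id = "m1", sequence = "AAGATC")
  expect_equal(nrow(find_motif_hits(m, seqs)), 1L)
  both <- find_motif_hits(m, seqs, both_strands = TRUE)
  expect_equal(nrow(both), 2L)  # its reverse complement GATCTT also occurs
  expect_setequal(both$strand, c("+", "-"))
})

.toy_exonic <- function() {
  data.frame(
    gene_id = c("gA", "gA", "gA", "gB", "gB", "gC"),
    motif_id = c("a", "b", "c", "b", "c", "d"),
    n_instances = c(1L, 2L, 1L, 1L, 1L, 3L),
    stringsAsFactors = FALSE)
}

test_that("motif partition reports Venn cells that conserve the motif total", {
  part <- partition_motifs(list(set1 = "gA", set2 = "gB", set3 = "gC"),
                           .toy_exonic())
  expect_setequal(part$per_set$set1, c("a", "b", "c"))
  expect_setequal(part$per_set$set2, c("b", "c"))
  expect_equal(part$per_set$set3, "d")
  expect_equal(unique_motifs(part, "set1"), "a")
  expect_setequal(part$cells$motifs[[which(part$cells$cell == "set1&set2")]],
                  c("b", "c"))
  # conservation: cell sizes sum to distinct motifs over the union
  expect_equal(sum(part$cells$n), 4L)
  # disjoint sets share nothing
  p2 <- partition_motifs(list(x = "gA", y = "gC"), .toy_exonic())
  expect_false(any(grepl("&", p2$cells$cell)))
  expect_warning(partition_motifs(list(x = c("gA", "missing")), .toy_exonic()),
                 "skipped")
})

test_that("per-gene pyknon density normalises by exonic length", {
  arch <- data.frame(gene_id = c("gA", "gB", "gC"),
                     exonic_length = c(10000L, 5000L, 2000L))
  prof <- gene_density_profile(arch, .toy_exonic())
  expect_equal(prof$distinct_motifs, c(3L, 2L, 1L))
  # 2 distinct motifs over 10 kb of exon would be density 2; gA has 3
  expect_equal(prof$density, c(3, 4, 5))
  expect_equal(prof$instances, c(4L, 2L, 3L))
  expect_equal(prof$density_alt, c(0.4, 0.4, 1.5))
  # restriction to a motif subset
  p2 <- gene_density_profile(arch, .toy_exonic(), motif_subset = c("b", "c"))
  expect_equal(p2$distinct_motifs, c(2L, 2L, 0L))
  expect_equal(p2$density[3L], 0)
})

test_that("family attribution: multi-family membership, empty sets, percentages", {
  ann <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(100, 500), c(200, 600)),
                                strand = c("+", "-"))
  ann$family <- c("SINE/Alu", "LINE/L1")
  ann$name <- c("AluY", "L1M5")
  hits <- data.frame(
    motif_id = c("m1", "m2", "m2", "m3"),
    seqname = "chr1",
    start = c(150L, 120L, 550L, 900L),
    end = c(160L, 130L, 560L, 910L),
    strand = "+", stringsAsFactors = FALSE)
  att <- attribute_to_families(hits, ann)
  expect_equal(att$per_motif$m1, "SINE/Alu")
  expect_setequal(att$per_motif$m2, c("SINE/Alu", "LINE/L1"))  # both families
  expect_equal(att$per_motif$m3, character())
  # percentages over motifs: 2/3 in Alu, 1/3 in L1 (sum > 100 is possible)
  expect_equal(att$summary$percent[att$summary$family == "SINE/Alu"], 200 / 3)
  # monotone: adding instances never removes membership
  ann2 <- c(ann, ann[1])
  att2 <- attribute_to_families(hits, ann2)
  expect_true(all(att$per_motif$m2 %in% att2$per_motif$m2))
})

test_that("density group comparison: symmetry, ties, planted shift", {
  set.seed(7)
  a <- runif(25, 0, 2)
  b <- a + 3
  r <- compare_density_groups(a, b)
  expect_lt(r$p, 0.05)
  expect_equal(compare_density_groups(b, a)$p, r$p)   # symmetric
  expect_warning(r0 <- compare_density_groups(rep(1, 5), rep(1, 8)), "tied")
  expect_equal(r0$p, 1)
  same <- compare_density_groups(a, a)
  expect_gt(same$p, 0.9)
})

test_that("family distribution comparison matches the chi-squared closed form", {
  # proportional vectors: statistic 0, p 1
  r0 <- compare_family_distributions(c(A = 10, B = 20, C = 30),
                                     c(A = 20, B = 40, C = 60))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p, 1)
  # hand-sized 2x3 table against the textbook formula
  a <- c(A = 12, B = 30, C = 8)
  b <- c(A = 20, B = 15, C = 25)
  tab <- rbind(a, b)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  r <- compare_family_distributions(a, b)
  expect_equal(r$statistic, stat)
  expect_equal(r$df, 2)
  # strongly divergent counts
  r2 <- compare_family_distributions(c(A = 500, B = 10), c(A = 10, B = 500))
  expect_lt(r2$p, 1e-5)
  expect_error(compare_family_distributions(c(A = 0), c(A = 5)), "zero-total")
})
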