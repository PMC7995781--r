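.mk_mat <- function(values, n_samples = 4, ids = NULL) {
  n <- length(values)
  if (is.null(ids)) ids <- sprintf("g%03d", seq_len(n))
  matrix(rep(values, n_samples), nrow = n,
         dimnames = list(ids, paste0("s", seq_len(n_samples))))
}

test_that("mean-based filters: counts, strictness, idempotence, ties", {
  m <- .mk_mat(c(1, 2, 3, 4))
  expect_equal(rownames(filter_bottom_mean(m, 0.25)),
               sprintf("g%03d", 2:4))
  m100 <- .mk_mat(seq_len(100))
  expect_equal(nrow(keep_top_expressed(m100, 0.5)), 50L)
  # mean exactly 2 removed (strictly "more than"), 2.01 kept
  m2 <- .mk_mat(c(2, 2.01, 5))
  expect_equal(rownames(mean_threshold_filter(m2, 2)),
               sprintf("g%03d", 2:3))
  # ties broken by gene id: deterministic
  mt <- .mk_mat(c(1, 1, 1, 5), ids = c("d", "c", "b", "a"))
  expect_equal(rownames(filter_bottom_mean(mt, 0.25)), c("d", "c", "a"))
  expect_identical(filter_bottom_mean(mt, 0.25),
                   filter_bottom_mean(mt, 0.25))
  # applying a threshold filter twice equals applying it once
  expect_identical(mean_threshold_filter(mean_threshold_filter(m2, 2), 2),
                   mean_threshold_filter(m2, 2))
})

test_that("fold-change DE: planted genes, symmetry, empty case", {
  set.seed(1)
  m <- matrix(10, nrow = 6, ncol = 6,
              dimnames = list(sprintf("g%d", 1:6),
                              c(paste0("a", 1:3), paste0("b", 1:3))))
  m["g1", 4:6] <- 40   # 4x up in B
  m["g2", 1:3] <- 25   # 2.5x down
  de <- fold_change_de(m, paste0("a", 1:3), paste0("b", 1:3))
  expect_equal(de$up, "g1")
  expect_equal(de$down, "g2")
  sw <- fold_change_de(m, paste0("b", 1:3), paste0("a", 1:3))
  expect_equal(sw$up, de$down)
  expect_equal(sw$down, de$up)
  m0 <- .mk_mat(c(5, 5), n_samples = 6)
  de0 <- fold_change_de(m0, paste0("s", 1:3), paste0("s", 4:6))
  expect_length(de0$up, 0L)
  expect_error(fold_change_de(m, "a1", "a1"), "disjoint")
})

test_that("permutation DE: null behaviour, planted recovery, label-swap", {
  # identical constant groups: nothing significant
  m0 <- .mk_mat(rep(3, 30), n_samples = 8)
  r0 <- permutation_de(m0, paste0("s", 1:4), paste0("s", 5:8),
                       n_perm = 200, seed = 1)
  expect_length(r0$up, 0L)
  expect_length(r0$down, 0L)

  set.seed(2)
  G <- 400; n <- 6
  m <- matrix(rnorm(G * 2 * n, 10), nrow = G,
              dimnames = list(sprintf("g%03d", 1:G),
                              c(paste0("a", 1:n), paste0("b", 1:n))))
  planted <- sprintf("g%03d", 1:40)
  m[planted, paste0("b", 1:n)] <- m[planted, paste0("b", 1:n)] + 3
  # 6 vs 6 gives 924 distinct label assignments (exhaustive), i.e. p-value
  # resolution 2/924, fine enough for BH at 5% with 10% planted genes
  r <- permutation_de(m, paste0("a", 1:n), paste0("b", 1:n),
                      n_perm = 1000, seed = 3)
  expect_gte(mean(planted %in% r$up), 0.8)             # recall
  fp <- setdiff(r$up, planted)
  expect_lte(length(fp) / max(1, length(r$up)), 0.1)   # empirical FDR

  # swapping labels flips effect signs, p unchanged
  r_sw <- permutation_de(m, paste0("b", 1:n), paste0("a", 1:n),
                         n_perm = 1000, seed = 3)
  expect_equal(r_sw$table$effect, -r$table$effect)
  expect_equal(r_sw$table$p, r$table$p)
  expect_equal(r_sw$up, r$down)
})

test_that("permutation DE p-values are near-uniform under the null", {
  set.seed(4)
  m <- matrix(rnorm(1000 * 10), nrow = 1000,
              dimnames = list(sprintf("g%04d", 1:1000),
                              c(paste0("a", 1:5), paste0("b", 1:5))))
  r <- permutation_de(m, paste0("a", 1:5), paste0("b", 1:5),
                      n_perm = 252, seed = 5)
  expect_gt(mean(r$table$p <= 0.05), 0.02)
  expect_lt(mean(r$table$p <= 0.05), 0.08)
  expect_length(r$up, 0L)
})

test_that("rank normalization: highest expression ranked 1, ties averaged", {
  m <- matrix(c(10, 30, 20), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), "s1"))
  expect_equal(as.numeric(rank_normalize(m)), c(3, 1, 2))
  # monotone transform invariance
  m2 <- m; m2[, 1] <- m[, 1]^3
  expect_equal(rank_normalize(m2), rank_normalize(m))
  mt <- matrix(c(5, 5, 1), nrow = 3,
               dimnames = list(c("g1", "g2", "g3"), "s1"))
  expect_equal(as.numeric(rank_normalize(mt)), c(1.5, 1.5, 3))
})

test_that("differential ranking: identity, invariance, planted shift", {
  set.seed(6)
  G <- 300
  base <- matrix(rlnorm(G * 12, 3, 1), nrow = G,
                 dimnames = list(sprintf("g%03d", 1:G), paste0("a", 1:12)))
  same <- base
  colnames(same) <- paste0("b", 1:12)
  r0 <- differential_rank(base, same, n_perm = 200, seed = 7)
  expect_length(r0$up, 0L)

  # per-sample monotone transforms of cohort B leave the result unchanged;
  # 12 vs 12 samples with 2000 sampled permutations give the p resolution
  # that BH at 1% requires (near-identity label assignments are then rare
  # enough not to floor the planted genes' p-values)
  planted <- sprintf("g%03d", 1:30)
  shifted <- base * matrix(rlnorm(G * 12, 0, 0.1), nrow = G)
  shifted[planted, ] <- shifted[planted, ] * 20
  colnames(shifted) <- paste0("b", 1:12)
  r1 <- differential_rank(base, shifted, n_perm = 2000, seed = 8)
  trans <- sweep(shifted^2, 2, c(1, 5, 0.2, 7, 3, 2, 0.5, 9, 4, 0.3, 6, 1.5), `*`)
  r2 <- differential_rank(base, trans, n_perm = 2000, seed = 8)
  expect_identical(r1, r2)
  expect_gte(mean(planted %in% r1$up), 0.8)
})

test_that("hypergeometric overlap matches the closed form", {
  u <- sprintf("u%02d", 1:10)
  expect_equal(hypergeometric_overlap(u[1:5], u[1:5], u), 1 / choose(10, 5))
  expect_equal(hypergeometric_overlap(u, u, u), 1)
  big <- sprintf("u%03d", 1:500)
  expect_gt(hypergeometric_overlap(big[1:5], big[6:10], big), 0.9)
  expect_error(hypergeometric_overlap("a", "a", character()), "empty")
  expect_error(hypergeometric_overlap("zz", u[1:2], u), "subsets")
})
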