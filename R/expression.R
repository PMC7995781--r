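#' Read an expression matrix from TSV
#'
#' First column gene ids, remaining columns samples; values are non-negative
#' abundances (FPKM/RPKM/TPM-like units).
#'
#' @param path input TSV file.
#' @return numeric matrix, genes x samples, rownames = gene ids.
#' @export
read_expression <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  .validate_expression(m)
}

.validate_expression <- function(m) {
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    stop("expression matrix needs unique gene-id rownames")
  }
  if (any(m < 0, na.rm = TRUE)) stop("negative abundance values")
  m
}

#' Read a sample-label table
#' @param path TSV with columns `sample` and `group` (or `tissue`).
#' @return named character vector: labels indexed by sample id.
#' @export
read_labels <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  grp_col <- intersect(c("group", "tissue", "label"), names(df))[1L]
  if (is.na(grp_col) || !"sample" %in% names(df)) {
    stop("label TSV needs a 'sample' and a 'group'/'tissue' column")
  }
  setNames(as.character(df[[grp_col]]), df$sample)
}

# Order gene ids decreasingly by mean with deterministic gene-id tie-break.
.order_by_mean <- function(m, decreasing = TRUE) {
  mu <- rowMeans(m)
  if (decreasing) {
    order(-mu, rownames(m), method = "radix")
  } else {
    order(mu, rownames(m), method = "radix")
  }
}

#' Remove the lowest-expressed fraction of genes
#'
#' Drops the `floor(fraction * n)` genes with lowest mean expression; ties at
#' the cutoff are broken by gene id so the result is deterministic.
#'
#' @param m expression matrix (genes x samples).
#' @param fraction fraction of genes to remove, in (0, 1); default 0.25.
#' @return the filtered matrix.
#' @export
filter_bottom_mean <- function(m, fraction = 0.25) {
  stopifnot(fraction > 0, fraction < 1)
  n_drop <- floor(fraction * nrow(m))
  if (n_drop == 0L) return(m)
  ord <- .order_by_mean(m, decreasing = FALSE)
  m[sort(ord[-seq_len(n_drop)]), , drop = FALSE]
}

#' Keep the top-expressed fraction of genes
#'
#' Keeps the `floor(fraction * n)` genes with highest mean expression
#' (deterministic gene-id tie-break).
#'
#' @inheritParams filter_bottom_mean
#' @param fraction fraction of genes to keep, in (0, 1); default 0.5.
#' @return the filtered matrix.
#' @export
keep_top_expressed <- function(m, fraction = 0.5) {
  stopifnot(fraction > 0, fraction < 1)
  n_keep <- floor(fraction * nrow(m))
  ord <- .order_by_mean(m, decreasing = TRUE)
  m[sort(ord[seq_len(n_keep)]), , drop = FALSE]
}

#' Keep genes above a mean-abundance threshold
#'
#' Keeps genes whose mean abundance across samples is strictly greater than
#' `threshold` (default 2, i.e. "more than 2 RPKM").
#'
#' @inheritParams filter_bottom_mean
#' @param threshold mean-abundance cutoff; default 2.
#' @return the filtered matrix.
#' @export
mean_threshold_filter <- function(m, threshold = 2) {
  m[rowMeans(m) > threshold, , drop = FALSE]
}

#' Fold-change differential expression
#'
#' Calls a gene up-regulated when `mean(B)/mean(A) >= fold` and
#' down-regulated when `mean(A)/mean(B) >= fold`. Zero means are stabilised
#' with a pseudo-count.
#'
#' @param m expression matrix.
#' @param group_a,group_b disjoint, non-empty character vectors of sample
#'   (column) names.
#' @param fold fold-change cutoff (default 2).
#' @param pseudo pseudo-count added to zero means (default 0.1).
#' @return list with character vectors `up` (higher in B) and `down`.
#' @export
fold_change_de <- function(m, group_a, group_b, fold = 2, pseudo = 0.1) {
  .check_groups(m, group_a, group_b)
  ma <- rowMeans(m[, group_a, drop = FALSE])
  mb <- rowMeans(m[, group_b, drop = FALSE])
  ma <- ifelse(ma == 0, pseudo, ma)
  mb <- ifelse(mb == 0, pseudo, mb)
  list(up = rownames(m)[mb / ma >= fold],
       down = rownames(m)[ma / mb >= fold])
}

.check_groups <- function(m, group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  missing <- setdiff(c(group_a, group_b), colnames(m))
  if (length(missing)) {
    stop("sample(s) not in matrix: ", paste(head(missing, 5L), collapse = ", "))
  }
}

#' Permutation test for differential abundance
#'
#' A two-sided permutation test on group-mean differences with a
#' variance-stabilising offset, standing in for significance analysis of
#' microarrays. Per gene, the statistic is
#' `d = (mean(B) - mean(A)) / (se + s0)` where `se` is the pooled standard
#' error and `s0` the median of all per-gene `se` values. Group labels are
#' permuted (`n_perm` random draws, or exhaustively when the number of
#' distinct label assignments does not exceed `n_perm`), and each gene's
#' two-sided p-value is the fraction of its own permuted `|d|` values that
#' reach its observed `|d|` (the identity assignment counts itself under
#' exhaustive enumeration, so p-values are never zero). P-values are
#' BH-corrected; genes at `fdr <= fdr_threshold` are split into up (higher
#' in B) and down sets by the sign of the effect.
#'
#' @param m expression (or rank) matrix, genes x samples.
#' @param group_a,group_b disjoint sample-name vectors (>= 2 samples each).
#' @param n_perm number of permutations (default 5000).
#' @param fdr_threshold FDR cutoff for the up/down sets (default 0.05).
#' @param seed optional integer seed.
#' @return list with `table` (a `data.frame`: `gene_id`, `effect`, `stat`,
#'   `p`, `fdr`), `up`, `down`.
#' @export
permutation_de <- function(m, group_a, group_b, n_perm = 5000,
                           fdr_threshold = 0.05, seed = NULL) {
  .check_groups(m, group_a, group_b)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 samples")
  }
  X <- m[, c(group_a, group_b), drop = FALSE]
  na <- length(group_a)
  nb <- length(group_b)
  n <- na + nb

  d_stat <- function(idx_a) {
    in_a <- logical(n)
    in_a[idx_a] <- TRUE
    xa <- X[, in_a, drop = FALSE]
    xb <- X[, !in_a, drop = FALSE]
    ma <- rowMeans(xa)
    mb <- rowMeans(xb)
    va <- rowSums((xa - ma)^2)
    vb <- rowSums((xb - mb)^2)
    sp <- sqrt((va + vb) / (n - 2) * (1 / na + 1 / nb))
    s0 <- median(sp)
    denom <- sp + s0
    denom[denom == 0] <- 1  # all-constant genes: statistic is the raw difference
    (mb - ma) / denom
  }

  obs <- d_stat(seq_len(na))

  if (!is.null(seed)) set.seed(seed)
  n_comb <- choose(n, na)
  exhaustive <- n_comb <= n_perm
  perms <- if (exhaustive) {
    combn(n, na, simplify = FALSE)
  } else {
    replicate(n_perm, sample.int(n, na), simplify = FALSE)
  }

  # per-gene counts of permuted |d| reaching the observed |d|
  tol <- .Machine$double.eps^0.5
  obs_abs <- abs(obs)
  ge <- integer(nrow(X))
  for (pm in perms) {
    ge <- ge + (abs(d_stat(pm)) >= obs_abs - tol)
  }
  p <- if (exhaustive) ge / length(perms) else (1 + ge) / (1 + length(perms))
  p <- pmin(p, 1)
  fdr <- bh_fdr(p)

  ma <- rowMeans(X[, seq_len(na), drop = FALSE])
  mb <- rowMeans(X[, na + seq_len(nb), drop = FALSE])
  tab <- data.frame(gene_id = rownames(m), effect = mb - ma, stat = obs,
                    p = p, fdr = fdr, row.names = NULL,
                    stringsAsFactors = FALSE)
  sig <- tab$fdr <= fdr_threshold
  list(table = tab,
       up = tab$gene_id[sig & tab$effect > 0],
       down = tab$gene_id[sig & tab$effect < 0])
}

#' Rank-normalize an expression matrix
#'
#' Within each sample, genes are ranked by abundance with the
#' highest-expressed gene ranked 1; ties receive the average rank. Ranks are
#' invariant to any per-sample strictly monotone transform of the raw
#' values, making them comparable across platforms.
#'
#' @param m expression matrix, genes x samples.
#' @return matrix of ranks with the same dimnames.
#' @export
rank_normalize <- function(m) {
  apply(m, 2L, function(x) rank(-x, ties.method = "average"))
}

#' Differential ranking between two cohorts
#'
#' Rank-normalizes each cohort per sample ([rank_normalize()]), then applies
#' [permutation_de()] to the combined rank matrix at the given FDR (default
#' 1%). Because the test runs on ranks, the result is invariant to
#' per-sample monotone transforms of the raw abundances. In the returned
#' sets, `up` contains genes with higher abundance (better rank, i.e.
#' numerically smaller) in cohort B.
#'
#' @param m_a,m_b expression matrices of the two cohorts over the same genes
#'   (>= 2 samples each).
#' @param n_perm number of permutations (default 5000).
#' @param fdr_threshold FDR cutoff (default 0.01).
#' @param seed optional integer seed.
#' @return as [permutation_de()]; effects are on the rank scale.
#' @export
differential_rank <- function(m_a, m_b, n_perm = 5000, fdr_threshold = 0.01,
                              seed = NULL) {
  if (!identical(rownames(m_a), rownames(m_b))) {
    common <- intersect(rownames(m_a), rownames(m_b))
    if (length(common) == 0L) stop("cohorts share no genes")
    m_a <- m_a[common, , drop = FALSE]
    m_b <- m_b[common, , drop = FALSE]
  }
  ra <- rank_normalize(m_a)
  rb <- rank_normalize(m_b)
  combined <- cbind(ra, rb)
  colnames(combined) <- c(paste0("A_", seq_len(ncol(ra))),
                          paste0("B_", seq_len(ncol(rb))))
  res <- permutation_de(combined,
                        group_a = colnames(combined)[seq_len(ncol(ra))],
                        group_b = colnames(combined)[ncol(ra) + seq_len(ncol(rb))],
                        n_perm = n_perm, fdr_threshold = fdr_threshold,
                        seed = seed)
  # on ranks, a negative effect (smaller rank in B) means higher abundance in B
  sig <- res$table$fdr <= fdr_threshold
  list(table = res$table,
       up = res$table$gene_id[sig & res$table$effect < 0],
       down = res$table$gene_id[sig & res$table$effect > 0])
}

#' Hypergeometric overlap test of two gene sets
#'
#' Upper-tail probability of observing at least the actual overlap between
#' two sets drawn from a finite universe (one-sided hypergeometric test, as
#' used for gene-set overlap significance).
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes (non-empty).
#' @return the p-value.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe) {
  if (length(universe) == 0L) stop("empty universe")
  universe <- unique(universe)
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    stop("sets must be subsets of the universe")
  }
  k <- length(intersect(set_a, set_b))
  phyper(k - 1L, length(set_a), length(universe) - length(set_a),
         length(set_b), lower.tail = FALSE)
}
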