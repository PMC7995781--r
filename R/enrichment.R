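#' Benjamini-Hochberg false discovery rate
#'
#' Step-up BH-adjusted p-values (monotone, capped at 1), via
#' [stats::p.adjust()].
#'
#' @param pvalues numeric vector of p-values in \[0, 1\]; may be empty.
#' @return adjusted values, same length.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric())
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Monte Carlo enrichment of repeat density in a gene set
#'
#' Tests, for every (family, region, orientation) stratum, whether the mean
#' repeat density of a target gene set deviates from what is expected for a
#' random set of the same size drawn from the background. In each of
#' `iterations` iterations a random subset of `|target|` genes is sampled
#' without replacement from the background and its mean density recorded for
#' every stratum (one shared gene resample per iteration). The resulting null
#' distribution yields, per stratum, an expected mean and SD, a Z-score for
#' the observed target mean, and a two-sided empirical p-value. A positive
#' Z-score means higher density than expected by chance (enrichment), a
#' negative one depletion. A two-sample Kolmogorov-Smirnov test of the target
#' vs background per-gene density distributions is reported alongside.
#' Empirical p-values are BH-corrected jointly across all evaluable strata;
#' a stratum is significant when `|z| >= z_threshold` and `fdr <=
#' fdr_threshold`. Strata whose null SD is zero are flagged non-evaluable
#' (`z` is undefined there) and excluded from the FDR correction.
#'
#' @param target_genes character vector of target gene ids (subset of
#'   `background_genes`).
#' @param background_genes character vector of background gene ids.
#' @param densities density table from [density_table()].
#' @param iterations number of Monte Carlo iterations (default 10000).
#' @param seed optional integer seed for reproducibility.
#' @param z_threshold absolute Z-score cutoff for significance (default 2).
#' @param fdr_threshold FDR cutoff for significance (default 0.05).
#' @return a `data.frame` with one row per stratum: `family`, `region`,
#'   `orientation`, `n_target`, `observed_mean`, `expected_mean`,
#'   `expected_sd`, `z`, `p_mc`, `ks_p`, `fdr`, `evaluable`, `significant`.
#' @export
mc_enrichment <- function(target_genes, background_genes, densities,
                          iterations = 10000, seed = NULL,
                          z_threshold = 2, fdr_threshold = 0.05) {
  if (iterations < 100) stop("iterations must be at least 100")
  target_genes <- unique(as.character(target_genes))
  background_genes <- unique(as.character(background_genes))
  if (!all(target_genes %in% background_genes)) {
    stop("target set is not a subset of the background")
  }
  if (length(background_genes) <= length(target_genes)) {
    stop("background must be larger than the target set for resampling")
  }
  dens <- densities[densities$gene_id %in% background_genes, , drop = FALSE]
  if (nrow(dens) == 0L) stop("no density records for the background genes")

  stratum <- interaction(dens$family, dens$region, dens$orientation,
                         drop = TRUE, sep = "\t")
  strata <- levels(stratum)
  n_bg <- length(background_genes)
  n_t <- length(target_genes)

  # background genes x strata density matrix; NA where a gene has no record
  # in a stratum (e.g. intron strata of intron-less genes)
  D <- matrix(NA_real_, nrow = n_bg, ncol = length(strata),
              dimnames = list(background_genes, strata))
  D[cbind(match(dens$gene_id, background_genes),
          match(as.character(stratum), strata))] <- dens$density

  in_target <- background_genes %in% target_genes
  observed <- colMeans(D[in_target, , drop = FALSE], na.rm = TRUE)

  if (!is.null(seed)) set.seed(seed)
  null_means <- matrix(NA_real_, nrow = iterations, ncol = length(strata))
  for (b in seq_len(iterations)) {
    idx <- sample.int(n_bg, n_t)
    null_means[b, ] <- colMeans(D[idx, , drop = FALSE], na.rm = TRUE)
  }

  expected_mean <- colMeans(null_means, na.rm = TRUE)
  expected_sd <- apply(null_means, 2L, sd, na.rm = TRUE)
  evaluable <- is.finite(expected_sd) & expected_sd > 0 & is.finite(observed)
  z <- ifelse(evaluable, (observed - expected_mean) / expected_sd, NA_real_)

  # two-sided empirical p from the resampling null (min tail x 2)
  p_mc <- rep(NA_real_, length(strata))
  for (j in seq_along(strata)) {
    if (!evaluable[j]) next
    nm <- null_means[, j]
    nm <- nm[is.finite(nm)]
    hi <- sum(nm >= observed[j])
    lo <- sum(nm <= observed[j])
    p_mc[j] <- min(1, 2 * (min(hi, lo) + 1) / (length(nm) + 1))
  }

  ks_p <- rep(NA_real_, length(strata))
  for (j in seq_along(strata)) {
    tv <- D[in_target, j]
    bv <- D[, j]
    tv <- tv[is.finite(tv)]; bv <- bv[is.finite(bv)]
    if (length(tv) >= 2L && length(bv) >= 2L) {
      ks_p[j] <- suppressWarnings(ks.test(tv, bv, exact = FALSE)$p.value)
    }
  }

  fdr <- rep(NA_real_, length(strata))
  fdr[evaluable] <- bh_fdr(p_mc[evaluable])
  significant <- evaluable & abs(z) >= z_threshold & fdr <= fdr_threshold
  significant[is.na(significant)] <- FALSE

  parts <- do.call(rbind, strsplit(strata, "\t", fixed = TRUE))
  out <- data.frame(
    family = parts[, 1L], region = parts[, 2L], orientation = parts[, 3L],
    n_target = n_t,
    observed_mean = as.numeric(observed),
    expected_mean = as.numeric(expected_mean),
    expected_sd = as.numeric(expected_sd),
    z = z, p_mc = p_mc, ks_p = ks_p, fdr = fdr,
    evaluable = evaluable, significant = significant,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out[order(out$family, out$region, out$orientation), , drop = FALSE]
}

#' Z-score heatmap matrix of enrichment results
#'
#' Arranges Z-scores as families x (region, orientation) columns, keeping
#' only families with at least one cell at `|z| >= z_threshold` (enrichment
#' or depletion). Non-evaluable cells are `NA`.
#'
#' @param results a `data.frame` from [mc_enrichment()].
#' @param z_threshold absolute Z-score row-retention cutoff (default 2).
#' @return a numeric matrix (possibly with zero rows) with columns
#'   `exon.sense`, `exon.antisense`, `intron.sense`, `intron.antisense`.
#' @export
heatmap_matrix <- function(results, z_threshold = 2) {
  cols <- c("exon.sense", "exon.antisense", "intron.sense", "intron.antisense")
  fams <- sort(unique(results$family))
  m <- matrix(NA_real_, nrow = length(fams), ncol = length(cols),
              dimnames = list(fams, cols))
  key <- paste(results$region, results$orientation, sep = ".")
  m[cbind(match(results$family, fams), match(key, cols))] <- results$z
  keep <- apply(m, 1L, function(r) any(abs(r) >= z_threshold, na.rm = TRUE))
  m[keep, , drop = FALSE]
}

#' Write an enrichment result table to TSV
#' @param results a `data.frame` from [mc_enrichment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
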