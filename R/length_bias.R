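#' Three-point moving average
#'
#' Centered moving average with window 3; at the two boundaries the window
#' shrinks to the available points, so the output has the same length as the
#' input and a constant sequence is unchanged.
#'
#' @param values numeric vector (length >= 1).
#' @return smoothed numeric vector of the same length.
#' @export
smooth3 <- function(values) {
  n <- length(values)
  if (n == 0L) stop("empty input")
  if (n == 1L) return(values)
  left <- c(NA, values[-n])
  right <- c(values[-1L], NA)
  s <- rowSums(cbind(left, values, right), na.rm = TRUE)
  k <- 3 - is.na(left) - is.na(right)
  s / k
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Two-sided two-sample KS test. The exact p-value is used for small,
#' tie-free samples (both sizes <= 50); the asymptotic approximation
#' otherwise.
#'
#' @param set_values,background_values numeric samples (each of size >= 2).
#' @return list with elements `statistic` and `p`.
#' @export
ks_compare <- function(set_values, background_values) {
  if (length(set_values) < 2L || length(background_values) < 2L) {
    stop("both samples must have at least 2 values")
  }
  if (length(unique(set_values)) < 2L && length(unique(background_values)) < 2L &&
      unique(set_values)[1L] == unique(background_values)[1L]) {
    stop("degenerate samples: all values identical")
  }
  pooled <- c(set_values, background_values)
  exact <- length(set_values) <= 50L && length(background_values) <= 50L &&
    !anyDuplicated(pooled)
  kt <- suppressWarnings(ks.test(set_values, background_values, exact = exact))
  list(statistic = unname(kt$statistic), p = unname(kt$p.value))
}

#' Cumulative-distribution difference curve of a gene set vs background
#'
#' Computes, on the pooled sorted unique values of both samples, the
#' difference between the background and the set empirical cumulative
#' distribution functions, `delta(x) = F_background(x) - F_set(x)`. With this
#' sign convention a set shifted towards larger values (e.g. longer exons)
#' gives positive delta. A 3-point moving average of delta is provided for
#' display; the KS statistic and p-value always refer to the unsmoothed
#' curve, and the maximum of `|delta|` equals the two-sample KS statistic.
#'
#' @param set_values numeric values of the gene set (non-empty).
#' @param background_values numeric values of the background (non-empty).
#' @return an object of class `CumulativeCurve`: a list with `grid`, `delta`,
#'   `delta_smooth`, `set_median`, `background_median`, `ks_statistic`,
#'   `ks_p`, `n_set`, `n_background`.
#' @export
cumulative_delta <- function(set_values, background_values) {
  if (length(set_values) == 0L || length(background_values) == 0L) {
    stop("both samples must be non-empty")
  }
  grid <- sort(unique(c(set_values, background_values)))
  F_set <- ecdf(set_values)
  F_bg <- ecdf(background_values)
  delta <- F_bg(grid) - F_set(grid)
  ks <- if (length(set_values) >= 2L && length(background_values) >= 2L) {
    ks_compare(set_values, background_values)
  } else {
    list(statistic = max(abs(delta)), p = NA_real_)
  }
  structure(list(
    grid = grid,
    delta = delta,
    delta_smooth = smooth3(delta),
    set_median = median(set_values),
    background_median = median(background_values),
    ks_statistic = ks$statistic,
    ks_p = ks$p,
    n_set = length(set_values),
    n_background = length(background_values)
  ), class = "CumulativeCurve")
}

#' @export
print.CumulativeCurve <- function(x, ...) {
  cat(sprintf(
    "CumulativeCurve: n_set=%d n_background=%d KS D=%.4f p=%.3g\n",
    x$n_set, x$n_background, x$ks_statistic, x$ks_p))
  cat(sprintf("  medians: set=%.4g background=%.4g; max|delta|=%.4f\n",
              x$set_median, x$background_median, max(abs(x$delta))))
  invisible(x)
}

#' Length-bias curve for one architectural measure
#'
#' Convenience wrapper: extracts one measure (`exonic_length`,
#' `intronic_length` or `exonic_content`) from an architecture table for a
#' gene set and its background and returns the [cumulative_delta()] curve.
#' Genes with zero intronic length are dropped for the `intronic_length`
#' measure.
#'
#' @param arch architecture table from [architecture()].
#' @param set_ids gene ids of the set.
#' @param measure one of `"exonic_length"`, `"intronic_length"`,
#'   `"exonic_content"`.
#' @param background_ids gene ids of the background (default: all genes in
#'   `arch`).
#' @return a `CumulativeCurve`.
#' @export
length_bias_curve <- function(arch, set_ids,
                              measure = c("exonic_length", "intronic_length",
                                          "exonic_content"),
                              background_ids = arch$gene_id) {
  measure <- match.arg(measure)
  a <- arch
  if (measure == "intronic_length") {
    a <- a[a$intronic_length > 0L, , drop = FALSE]
  }
  sv <- a[[measure]][a$gene_id %in% set_ids]
  bv <- a[[measure]][a$gene_id %in% background_ids]
  if (length(sv) == 0L) stop("gene set has no usable values for ", measure)
  cumulative_delta(sv, bv)
}

#' Write a cumulative curve to TSV
#' @param curve a `CumulativeCurve`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  df <- data.frame(value = curve$grid, delta = curve$delta,
                   delta_smooth = curve$delta_smooth)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
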