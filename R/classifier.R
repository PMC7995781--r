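#' Binarize an expression matrix
#'
#' Per sample, genes with abundance strictly greater than `min_abundance`
#' are candidates; the `k = round-half-up(top_fraction * n_candidates)`
#' candidates of highest abundance are called expressed, every other gene
#' not expressed. Ties are broken by abundance, then gene id, so the result
#' is deterministic, and the call is invariant to any per-sample strictly
#' monotone transform of the abundances above the threshold.
#'
#' @param m expression matrix, genes x samples.
#' @param min_abundance candidate threshold (default 2, i.e. > 2 FPKM).
#' @param top_fraction fraction of candidates called expressed (default 0.5).
#' @return logical matrix of the same dimensions (`TRUE` = expressed).
#' @export
binarize <- function(m, min_abundance = 2, top_fraction = 0.5) {
  .validate_expression(m)
  out <- matrix(FALSE, nrow = nrow(m), ncol = ncol(m), dimnames = dimnames(m))
  ids <- rownames(m)
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    cand <- which(x > min_abundance)
    if (length(cand) == 0L) {
      warning("sample '", colnames(m)[j], "' has no candidate genes (all <= ",
              min_abundance, ")")
      next
    }
    k <- floor(top_fraction * length(cand) + 0.5)  # round half up
    if (k == 0L) next
    ord <- cand[order(-x[cand], ids[cand], method = "radix")]
    out[ord[seq_len(k)], j] <- TRUE
  }
  out
}

.split_samples <- function(binary, labels) {
  if (is.null(colnames(binary))) stop("binary matrix needs sample colnames")
  missing <- setdiff(colnames(binary), names(labels))
  if (length(missing)) {
    stop("sample(s) without labels: ", paste(head(missing, 5L), collapse = ", "))
  }
  split(colnames(binary), labels[colnames(binary)])
}

#' Flag widely expressed genes
#'
#' Genes called expressed in more than `fraction` of the samples within
#' every tissue are widely expressed: they cannot be part of a
#' tissue-specific signature and are excluded from the machine learning.
#'
#' @param binary logical matrix from [binarize()].
#' @param labels named character vector: tissue per sample.
#' @param fraction within-tissue expressed fraction (default 0.9).
#' @return character vector of widely expressed gene ids.
#' @export
flag_widely_expressed <- function(binary, labels, fraction = 0.9) {
  by_tissue <- .split_samples(binary, labels)
  frac <- vapply(by_tissue, function(s)
    rowMeans(binary[, s, drop = FALSE]), numeric(nrow(binary)))
  rownames(binary)[apply(frac > fraction, 1L, all)]
}

#' Filter uninformative genes
#'
#' With `rule = "literal"` (default), removes genes that are called not
#' expressed in fewer than `fraction` of the samples within every tissue --
#' i.e. genes expressed in most samples of every tissue, which carry no
#' tissue-discriminating signal. `rule = "any_tissue"` is stricter and
#' removes a gene when this holds in at least one tissue.
#'
#' @param binary logical matrix from [binarize()].
#' @param labels named character vector: tissue per sample.
#' @param fraction not-expressed fraction cutoff (default 0.5).
#' @param rule `"literal"` or `"any_tissue"`.
#' @return character vector of retained gene ids.
#' @export
filter_uninformative <- function(binary, labels, fraction = 0.5,
                                 rule = c("literal", "any_tissue")) {
  rule <- match.arg(rule)
  by_tissue <- .split_samples(binary, labels)
  not_frac <- vapply(by_tissue, function(s)
    rowMeans(!binary[, s, drop = FALSE]), numeric(nrow(binary)))
  below <- not_frac < fraction
  drop <- if (rule == "literal") apply(below, 1L, all) else apply(below, 1L, any)
  rownames(binary)[!drop]
}

.pair_weights <- function(fit) {
  w <- crossprod(fit$coefs, fit$SV)  # 1 x n_features
  as.numeric(w)
}

.fit_pair <- function(X, y, cost) {
  # X: samples x genes (numeric 0/1), y: factor with 2 levels
  e1071::svm(x = X, y = y, kernel = "linear", cost = cost, scale = FALSE)
}

.vote_predict <- function(pair_fits, pairs, tissues, X) {
  votes <- matrix(0L, nrow = nrow(X), ncol = length(tissues),
                  dimnames = list(rownames(X), tissues))
  for (i in seq_along(pair_fits)) {
    pred <- as.character(predict(pair_fits[[i]], X))
    votes[cbind(seq_len(nrow(X)), match(pred, tissues))] <-
      votes[cbind(seq_len(nrow(X)), match(pred, tissues))] + 1L
  }
  prob <- votes / (length(tissues) - 1L)
  best <- max.col(prob, ties.method = "first")
  data.frame(
    sample = rownames(X),
    predicted = tissues[best],
    probability = prob[cbind(seq_len(nrow(X)), best)],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Train a one-vs-one linear SVM tissue model with cross-validation
#'
#' Trains one linear support-vector machine per tissue pair on binarized
#' expression features (0/1) and classifies samples by voting: the
#' probability of a tissue is its share of pairwise votes, `votes /
#' (n_tissues - 1)`. A sample whose top probability is strictly below
#' `other_threshold` is assigned to the rejection class `"Other"`.
#' Performance is estimated by stratified k-fold cross-validation (folds
#' seeded); the confusion matrix reports row percentages of true tissue vs
#' predicted tissue (including Other), averaged over folds. The returned
#' model is refit on all samples for downstream prediction and variable
#' importance.
#'
#' @param binary logical (or 0/1) matrix from [binarize()], genes x samples,
#'   already reduced to the informative genes.
#' @param labels named character vector: tissue per sample.
#' @param folds number of cross-validation folds (default 10).
#' @param seed optional integer seed for fold assignment.
#' @param cost SVM regularization parameter C (default 1).
#' @param other_threshold probability below which a sample is assigned to
#'   `"Other"` (default 0.5).
#' @return an object of class `ovo_svm`: list with `tissues`, `pairs`,
#'   `fits`, `weights` (pairs x genes matrix), `cv` (per-sample held-out
#'   predictions), `confusion` (row-percent matrix), `accuracy` (held-out
#'   accuracy, Other counted as an error), `folds`, `cost`,
#'   `other_threshold`.
#' @export
train_ovo_linear <- function(binary, labels, folds = 10, seed = NULL,
                             cost = 1, other_threshold = 0.5) {
  X <- t(binary * 1)  # samples x genes
  by_tissue <- .split_samples(binary, labels)
  tissues <- sort(names(by_tissue))
  if (length(tissues) < 2L) stop("need at least 2 tissues")
  small <- tissues[vapply(by_tissue[tissues], length, 1L) < folds]
  if (length(small)) {
    stop("tissue(s) with fewer samples than folds (use fewer folds): ",
         paste(small, collapse = ", "))
  }
  y_all <- labels[rownames(X)]

  if (!is.null(seed)) set.seed(seed)
  fold_of <- setNames(integer(nrow(X)), rownames(X))
  for (t in tissues) {
    s <- sample(by_tissue[[t]])
    fold_of[s] <- rep_len(seq_len(folds), length(s))
  }

  pairs <- combn(tissues, 2L, simplify = FALSE)
  fit_pairs <- function(sample_ids) {
    lapply(pairs, function(pr) {
      ids <- sample_ids[y_all[sample_ids] %in% pr]
      .fit_pair(X[ids, , drop = FALSE],
                factor(y_all[ids], levels = pr), cost)
    })
  }

  cv_rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    test_ids <- names(fold_of)[fold_of == f]
    train_ids <- names(fold_of)[fold_of != f]
    fits_f <- fit_pairs(train_ids)
    pred <- .vote_predict(fits_f, pairs, tissues, X[test_ids, , drop = FALSE])
    pred$predicted[pred$probability < other_threshold] <- "Other"
    pred$fold <- f
    pred$true <- unname(y_all[pred$sample])
    cv_rows[[f]] <- pred
  }
  cv <- do.call(rbind, cv_rows)

  lev_pred <- c(tissues, "Other")
  conf_sum <- matrix(0, nrow = length(tissues), ncol = length(lev_pred),
                     dimnames = list(tissues, lev_pred))
  for (f in seq_len(folds)) {
    cf <- cv[cv$fold == f, ]
    tab <- table(factor(cf$true, levels = tissues),
                 factor(cf$predicted, levels = lev_pred))
    rs <- rowSums(tab)
    rs[rs == 0] <- 1
    conf_sum <- conf_sum + 100 * unclass(tab) / rs
  }
  confusion <- conf_sum / folds

  fits_all <- fit_pairs(rownames(X))
  weights <- do.call(rbind, lapply(fits_all, .pair_weights))
  rownames(weights) <- vapply(pairs, paste, "", collapse = ".vs.")
  colnames(weights) <- colnames(X)

  structure(list(
    tissues = tissues, pairs = pairs, fits = fits_all, weights = weights,
    cv = cv, confusion = confusion,
    accuracy = mean(cv$predicted == cv$true),
    folds = folds, cost = cost, other_threshold = other_threshold
  ), class = "ovo_svm")
}

#' @export
print.ovo_svm <- function(x, ...) {
  cat(sprintf(
    "ovo_svm: %d tissues, %d pairwise models, %d genes; CV accuracy %.1f%%\n",
    length(x$tissues), length(x$pairs), ncol(x$weights), 100 * x$accuracy))
  invisible(x)
}

#' Predict tissue (or Other) for new samples
#'
#' Applies the pairwise models of a trained [train_ovo_linear()] model to
#' new binarized samples. The most-voted tissue is assigned unless its vote
#' probability is strictly below `threshold`, in which case the sample goes
#' to `"Other"`.
#'
#' @param model an `ovo_svm` object.
#' @param binary logical (or 0/1) matrix, genes x samples, with the model's
#'   genes as rows.
#' @param threshold rejection threshold (default: the model's).
#' @return a `data.frame` with `sample`, `predicted`, `probability`.
#' @export
predict_with_other <- function(model, binary, threshold = model$other_threshold) {
  if (!inherits(model, "ovo_svm")) stop("model must be an ovo_svm object")
  missing <- setdiff(colnames(model$weights), rownames(binary))
  if (length(missing)) {
    stop("binary matrix lacks model gene(s): ",
         paste(head(missing, 5L), collapse = ", "))
  }
  X <- t(binary[colnames(model$weights), , drop = FALSE] * 1)
  pred <- .vote_predict(model$fits, model$pairs, model$tissues, X)
  pred$predicted[pred$probability < threshold] <- "Other"
  pred
}

#' Variable importance of a one-vs-one SVM model
#'
#' The variable importance (VI) of a gene is the mean of its squared weights
#' across all pairwise linear models. Genes are ranked by decreasing VI
#' (ties broken by gene id).
#'
#' @param model an `ovo_svm` object (or any list with a `weights` matrix of
#'   pairwise models x genes).
#' @return a `data.frame` with `gene_id`, `vi`, `rank`, sorted by rank.
#' @export
variable_importance <- function(model) {
  w <- model$weights
  if (is.null(w)) stop("model carries no weight matrix")
  vi <- colMeans(w^2)
  ord <- order(-vi, colnames(w), method = "radix")
  data.frame(gene_id = colnames(w)[ord], vi = unname(vi[ord]),
             rank = seq_along(vi), row.names = NULL, stringsAsFactors = FALSE)
}
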