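#' Configuration for the gene-architecture bias pipeline
#'
#' Bundles input paths and stage parameters for [run_bias_analysis()].
#' Defaults are the canonical analysis settings: 10,000 Monte Carlo
#' iterations, absolute Z-score threshold 2, FDR 5%.
#'
#' @param gtf path to the gene annotation GTF.
#' @param rmsk path to the repeat annotation.
#' @param rmsk_dialect `"out"` or `"rmsk"`.
#' @param gene_sets named list of gene-set file paths (or character vectors
#'   of gene ids).
#' @param background optional gene-set file path/vector; default: all genes
#'   in the GTF.
#' @param measures architectural measures for the length-bias curves.
#' @param iterations,z_threshold,fdr_threshold Monte Carlo parameters.
#' @param seed integer seed.
#' @param outdir output directory.
#' @return a list of class `bias_config`.
#' @export
bias_config <- function(gtf, rmsk, rmsk_dialect = c("rmsk", "out"),
                        gene_sets, background = NULL,
                        measures = c("exonic_length", "intronic_length",
                                     "exonic_content"),
                        iterations = 10000, z_threshold = 2,
                        fdr_threshold = 0.05, seed = 1, outdir = ".") {
  rmsk_dialect <- match.arg(rmsk_dialect)
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    stop("gene_sets must be a named list")
  }
  structure(list(gtf = gtf, rmsk = rmsk, rmsk_dialect = rmsk_dialect,
                 gene_sets = gene_sets, background = background,
                 measures = measures, iterations = iterations,
                 z_threshold = z_threshold, fdr_threshold = fdr_threshold,
                 seed = seed, outdir = outdir),
            class = "bias_config")
}

.resolve_set <- function(x) {
  if (length(x) == 1L && is.character(x) && file.exists(x)) read_gene_set(x)
  else as.character(x)
}

.write_manifest <- function(outdir, stage, params) {
  manifest <- list(
    stage = stage,
    package = "archrep",
    version = as.character(packageVersion("archrep")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = params
  )
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

.stage <- function(name, expr, quiet) {
  if (!quiet) message("[archrep] stage: ", name)
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the gene-architecture and repeat-density bias analysis
#'
#' End-to-end composition: read gene models and repeat annotation, compute
#' the architecture table and per-gene density table, and, for every gene
#' set, the length-bias curves (one per measure) and the Monte Carlo
#' enrichment table with its Z-score heatmap matrix. All tables are written
#' to `outdir` together with a run manifest (seed, package version, every
#' parameter). Deterministic given the config seed.
#'
#' @param config a [bias_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `architecture`, `densities`, `curves`
#'   (per set, per measure), `enrichment` (per set), `heatmaps` (per set),
#'   `files`.
#' @export
run_bias_analysis <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "bias_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  gm <- .stage("read_gene_models", read_gene_models(config$gtf), quiet)
  arch <- .stage("architecture", architecture(gm), quiet)
  annot <- .stage("read_repeatmasker",
                  read_repeatmasker(config$rmsk, dialect = config$rmsk_dialect),
                  quiet)
  dens <- .stage("density_table", density_table(gm, annot), quiet)

  background <- if (is.null(config$background)) arch$gene_id
                else .resolve_set(config$background)

  files <- c(architecture = file.path(config$outdir, "architecture.tsv"),
             densities = file.path(config$outdir, "densities.tsv"))
  write_architecture(arch, files[["architecture"]])
  write_density_table(dens, files[["densities"]])

  curves <- list()
  enrichment <- list()
  heatmaps <- list()
  for (set_name in names(config$gene_sets)) {
    set_ids <- .resolve_set(config$gene_sets[[set_name]])
    if (length(set_ids) == 0L) {
      stop("gene set '", set_name, "' is empty")
    }
    curves[[set_name]] <- list()
    for (measure in config$measures) {
      cv <- .stage(paste0("length_bias:", set_name, ":", measure),
                   length_bias_curve(arch, set_ids, measure = measure,
                                     background_ids = background),
                   quiet)
      curves[[set_name]][[measure]] <- cv
      f <- file.path(config$outdir,
                     sprintf("curve_%s_%s.tsv", set_name, measure))
      write_curve(cv, f)
      files[[paste("curve", set_name, measure, sep = "_")]] <- f
    }
    enr <- .stage(paste0("mc_enrichment:", set_name),
                  mc_enrichment(intersect(set_ids, background), background,
                                dens, iterations = config$iterations,
                                seed = .substream(config$seed,
                                                  paste0("mc_", set_name)),
                                z_threshold = config$z_threshold,
                                fdr_threshold = config$fdr_threshold),
                  quiet)
    enrichment[[set_name]] <- enr
    heatmaps[[set_name]] <- heatmap_matrix(enr, config$z_threshold)
    f <- file.path(config$outdir, sprintf("enrichment_%s.tsv", set_name))
    write_enrichment(enr, f)
    files[[paste0("enrichment_", set_name)]] <- f
    f <- file.path(config$outdir, sprintf("heatmap_%s.tsv", set_name))
    write.table(heatmaps[[set_name]], f, sep = "\t", quote = FALSE,
                col.names = NA)
    files[[paste0("heatmap_", set_name)]] <- f
  }

  .write_manifest(config$outdir, "bias_analysis",
                  config[setdiff(names(config), "gene_sets")])
  invisible(list(architecture = arch, densities = dens, curves = curves,
                 enrichment = enrichment, heatmaps = heatmaps, files = files))
}

#' Configuration for the tissue-signature pipeline
#'
#' @param expression path to the expression TSV (or a matrix).
#' @param labels path to the sample-label TSV (or a named vector).
#' @param min_abundance binarization candidate threshold (default 2 FPKM).
#' @param top_fraction binarization expressed fraction (default 0.5).
#' @param widely_fraction widely-expressed cutoff (default 0.9).
#' @param uninformative_fraction uninformative-gene cutoff (default 0.5).
#' @param folds cross-validation folds (default 10).
#' @param cost SVM regularization parameter (default 1).
#' @param other_threshold rejection-class probability threshold (default 0.5).
#' @param seed integer seed.
#' @param outdir output directory.
#' @return a list of class `signature_config`.
#' @export
signature_config <- function(expression, labels, min_abundance = 2,
                             top_fraction = 0.5, widely_fraction = 0.9,
                             uninformative_fraction = 0.5, folds = 10,
                             cost = 1, other_threshold = 0.5,
                             seed = 1, outdir = ".") {
  structure(list(expression = expression, labels = labels,
                 min_abundance = min_abundance, top_fraction = top_fraction,
                 widely_fraction = widely_fraction,
                 uninformative_fraction = uninformative_fraction,
                 folds = folds, cost = cost,
                 other_threshold = other_threshold, seed = seed,
                 outdir = outdir),
            class = "signature_config")
}

#' Run the binarized-expression tissue-signature analysis
#'
#' Binarizes the expression matrix, removes widely expressed and
#' uninformative genes, trains the one-vs-one linear SVM with stratified
#' cross-validation, and writes the binary matrix, variable-importance
#' table, confusion matrix, held-out predictions and a run manifest.
#'
#' @param config a [signature_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with `binary`, `widely_expressed`, `retained`,
#'   `model`, `vi`, `confusion`, `files`.
#' @export
run_signature_analysis <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "signature_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  m <- if (is.matrix(config$expression)) config$expression
       else .stage("read_expression", read_expression(config$expression), quiet)
  labels <- if (is.character(config$labels) && length(config$labels) == 1L &&
                file.exists(config$labels)) {
    .stage("read_labels", read_labels(config$labels), quiet)
  } else config$labels

  binary <- .stage("binarize",
                   binarize(m, config$min_abundance, config$top_fraction),
                   quiet)
  widely <- .stage("flag_widely_expressed",
                   flag_widely_expressed(binary, labels,
                                         config$widely_fraction), quiet)
  retained <- .stage("filter_uninformative",
                     filter_uninformative(binary, labels,
                                          config$uninformative_fraction),
                     quiet)
  retained <- setdiff(retained, widely)
  model <- .stage("train_ovo_linear",
                  train_ovo_linear(binary[retained, , drop = FALSE], labels,
                                   folds = config$folds,
                                   seed = .substream(config$seed, "folds"),
                                   cost = config$cost,
                                   other_threshold = config$other_threshold),
                  quiet)
  vi <- variable_importance(model)

  files <- c(binary = file.path(config$outdir, "binary_matrix.tsv"),
             vi = file.path(config$outdir, "vi_table.tsv"),
             confusion = file.path(config$outdir, "confusion.tsv"),
             predictions = file.path(config$outdir, "cv_predictions.tsv"))
  write.table(data.frame(gene_id = rownames(binary), binary * 1L,
                         check.names = FALSE),
              files[["binary"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(vi, files[["vi"]], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(model$confusion, files[["confusion"]], sep = "\t",
              quote = FALSE, col.names = NA)
  write.table(model$cv, files[["predictions"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  .write_manifest(config$outdir, "signature_analysis",
                  config[setdiff(names(config), c("expression", "labels"))])
  invisible(list(binary = binary, widely_expressed = widely,
                 retained = retained, model = model, vi = vi,
                 confusion = model$confusion, files = files))
}
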