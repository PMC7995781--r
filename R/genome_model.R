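#' @import methods
#' @importFrom stats median sd setNames rlnorm runif rbeta rgeom
#'   ks.test wilcox.test chisq.test p.adjust phyper ecdf aggregate predict
#' @importFrom utils read.table write.table combn head packageVersion
NULL

#' Gene models: stranded genes with exon intervals
#'
#' A `GeneModels` object holds, for a set of genes, the genomic span of each
#' gene and its exon intervals. Coordinates follow the GRanges convention
#' (1-based, closed). All exons of a gene must lie on the gene's chromosome
#' and strand and fall within its span; genes violating this are rejected.
#'
#' @param exons a `data.frame` with columns `gene_id`, `chrom`, `start`,
#'   `end`, `strand` (1-based closed coordinates), or a [GenomicRanges::GRanges]
#'   with a `gene_id` metadata column.
#' @param spans optional `data.frame`/`GRanges` of gene spans in the same form
#'   (one row per gene). When omitted, each gene's span is the range of its
#'   exons.
#' @return an object of class `GeneModels` with elements `genes` (a named
#'   `GRanges` of spans) and `exons` (a named `GRangesList`, exons sorted by
#'   start).
#' @export
GeneModels <- function(exons, spans = NULL) {
  exons <- .as_gene_granges(exons)
  if (length(exons) == 0L) stop("no exons supplied")
  exons_by <- GenomicRanges::split(exons, exons$gene_id)
  ids <- names(exons_by)

  chrom_n <- vapply(
    GenomicRanges::seqnames(exons_by),
    function(x) length(unique(as.character(S4Vectors::runValue(x)))), 1L
  )
  strand_n <- vapply(
    GenomicRanges::strand(exons_by),
    function(x) length(unique(as.character(S4Vectors::runValue(x)))), 1L
  )
  bad <- ids[chrom_n > 1L | strand_n > 1L]
  if (length(bad)) {
    stop("gene(s) with exons on multiple chromosomes or strands: ",
         paste(bad, collapse = ", "))
  }
  bad_strand <- ids[vapply(GenomicRanges::strand(exons_by), function(x)
    any(as.character(S4Vectors::runValue(x)) == "*"), TRUE)]
  if (length(bad_strand)) {
    stop("gene(s) without a strand: ", paste(bad_strand, collapse = ", "))
  }

  exons_by <- GenomicRanges::sort(exons_by)

  if (is.null(spans)) {
    genes <- unlist(range(exons_by))
    genes$gene_id <- names(genes)
  } else {
    genes <- .as_gene_granges(spans)
    if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id in spans")
    names(genes) <- genes$gene_id
    missing <- setdiff(ids, genes$gene_id)
    if (length(missing)) {
      stop("exons with no gene span: ", paste(missing, collapse = ", "))
    }
    genes <- genes[ids]
    ex_rng <- unlist(range(exons_by))
    outside <- ids[GenomicRanges::start(ex_rng) < GenomicRanges::start(genes) |
                   GenomicRanges::end(ex_rng) > GenomicRanges::end(genes) |
                   as.character(GenomicRanges::seqnames(ex_rng)) !=
                     as.character(GenomicRanges::seqnames(genes)) |
                   as.character(GenomicRanges::strand(ex_rng)) !=
                     as.character(GenomicRanges::strand(genes))]
    if (length(outside)) {
      stop("exon outside its gene span (or on another chrom/strand) for: ",
           paste(outside, collapse = ", "))
    }
  }

  structure(list(genes = genes, exons = exons_by), class = "GeneModels")
}

.as_gene_granges <- function(x) {
  if (inherits(x, "GRanges")) {
    if (is.null(x$gene_id)) stop("GRanges input must carry a gene_id column")
    return(x)
  }
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(x$end < x$start)) stop("interval with end < start")
  gr <- GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start, end = x$end),
    strand = x$strand
  )
  gr$gene_id <- as.character(x$gene_id)
  gr
}

#' @export
print.GeneModels <- function(x, ...) {
  cat("GeneModels:", length(x$genes), "genes,",
      sum(lengths(x$exons)), "exons\n")
  invisible(x)
}

#' @export
length.GeneModels <- function(x) length(x$genes)

#' Gene identifiers of a GeneModels object
#' @param gm a `GeneModels` object.
#' @return character vector of gene ids.
#' @export
gene_ids <- function(gm) names(gm$genes)

#' Read gene models from a GTF file
#'
#' Parses an ENSEMBL-dialect GTF (features `gene` and `exon`, attributes
#' `gene_id` and, if present, `gene_biotype`) into a [GeneModels] object.
#' When a gene has multiple transcripts, all their exons are kept; downstream
#' the exonic region is the union of all exons. Genes with a `gene` feature
#' but no exon lines are dropped; genes with exons but no `gene` line get the
#' exon range as their span.
#'
#' @param path path to a GTF file.
#' @param protein_coding_only keep only genes with
#'   `gene_biotype == "protein_coding"` (default `TRUE`; ignored when the file
#'   carries no biotype attribute).
#' @return a [GeneModels] object.
#' @export
read_gene_models <- function(path, protein_coding_only = TRUE) {
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("failed to parse GTF '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(gr$type) || is.null(gr$gene_id)) {
    stop("GTF lacks 'type' or 'gene_id' information: ", path)
  }
  if (protein_coding_only && !is.null(gr$gene_biotype)) {
    coding_ids <- unique(gr$gene_id[!is.na(gr$gene_biotype) &
                                      gr$gene_biotype == "protein_coding"])
    gr <- gr[gr$gene_id %in% coding_ids]
  }
  ex <- gr[gr$type == "exon"]
  gn <- gr[gr$type == "gene"]
  if (length(ex) == 0L) stop("GTF contains no exon features: ", path)
  gn <- gn[gn$gene_id %in% unique(ex$gene_id)]
  spans <- NULL
  if (length(gn)) {
    spans <- gn[, "gene_id"]
    extra <- setdiff(unique(ex$gene_id), gn$gene_id)
    if (length(extra)) {
      ex_extra <- ex[ex$gene_id %in% extra]
      rng <- unlist(range(GenomicRanges::split(ex_extra, ex_extra$gene_id)))
      rng$gene_id <- names(rng)
      spans <- c(spans, rng)
    }
  }
  GeneModels(ex[, "gene_id"], spans = spans)
}

.subset_ids <- function(gm, gene_ids) {
  if (is.null(gene_ids)) return(gm)
  missing <- setdiff(gene_ids, names(gm$genes))
  if (length(missing)) {
    stop("unknown gene id(s): ", paste(head(missing, 5L), collapse = ", "))
  }
  structure(list(genes = gm$genes[gene_ids], exons = gm$exons[gene_ids]),
            class = "GeneModels")
}

#' Exonic region of each gene
#'
#' The exonic region of a gene is the union of its exons: overlapping and
#' adjacent exons are merged into maximal disjoint intervals.
#'
#' @param gm a [GeneModels] object.
#' @param gene_ids optional character vector restricting the genes.
#' @return a named `GRangesList`, one reduced interval set per gene.
#' @export
exonic_region <- function(gm, gene_ids = NULL) {
  gm <- .subset_ids(gm, gene_ids)
  GenomicRanges::reduce(gm$exons)
}

#' Intronic region of each gene
#'
#' The intronic region is the gene's genomic span minus its exonic region;
#' it is empty for single-exon genes whose exon covers the span.
#'
#' @inheritParams exonic_region
#' @return a named `GRangesList` (possibly with empty elements).
#' @export
intronic_region <- function(gm, gene_ids = NULL) {
  gm <- .subset_ids(gm, gene_ids)
  GenomicRanges::psetdiff(gm$genes, GenomicRanges::reduce(gm$exons))
}

#' Gene architecture table
#'
#' Computes, per gene, the span length, exonic length (bases covered by the
#' union of exons), intronic length (span minus exonic), and exonic content
#' (exonic length divided by span length) -- the fraction of the gene's
#' genomic span taken up by its exons, a measure of gene compactness.
#' Exonic and intronic length always sum to the span length.
#'
#' @inheritParams exonic_region
#' @return a `data.frame` with columns `gene_id`, `chrom`, `strand`,
#'   `span_length`, `exonic_length`, `intronic_length`, `exonic_content`.
#' @export
architecture <- function(gm, gene_ids = NULL) {
  gm <- .subset_ids(gm, gene_ids)
  span_len <- GenomicRanges::width(gm$genes)
  ex_len <- sum(GenomicRanges::width(GenomicRanges::reduce(gm$exons)))
  data.frame(
    gene_id = names(gm$genes),
    chrom = as.character(GenomicRanges::seqnames(gm$genes)),
    strand = as.character(GenomicRanges::strand(gm$genes)),
    span_length = span_len,
    exonic_length = as.integer(ex_len),
    intronic_length = as.integer(span_len - ex_len),
    exonic_content = as.numeric(ex_len) / span_len,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write an architecture table to TSV
#' @param arch a `data.frame` from [architecture()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_architecture <- function(arch, path) {
  write.table(arch, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-set file (one gene id per line)
#' @param path text file with one gene id per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return character vector of gene ids.
#' @export
read_gene_set <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !startsWith(x, "#")]
}
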