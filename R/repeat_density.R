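#' Read RepeatMasker annotation
#'
#' Reads repeat instances from RepeatMasker output, either the native `.out`
#' format (three header lines, whitespace-separated columns, strand `C`
#' meaning the complement strand) or a UCSC rmsk-style TSV with columns
#' `genoName`, `genoStart`, `genoEnd`, `strand`, `repName`, `repClass`,
#' `repFamily`. Family labels are `repClass/repFamily` (e.g. `SINE/Alu`);
#' when class and family coincide the class alone is used. Low-confidence
#' families (any label containing `?`) and the `Simple_repeat` and
#' `Low_complexity` classes are excluded on read.
#'
#' `.out` coordinates are 1-based closed; rmsk TSV coordinates are 0-based
#' half-open (UCSC convention). Both are converted to the 1-based GRanges
#' convention on read.
#'
#' @param path path to the annotation file.
#' @param dialect `"out"` or `"rmsk"`.
#' @param family_level `"family"` (default, `repClass/repFamily`) or
#'   `"class"` (repClass only).
#' @return a `GRanges` with metadata columns `family` and `name`.
#' @export
read_repeatmasker <- function(path, dialect = c("out", "rmsk"),
                              family_level = c("family", "class")) {
  dialect <- match.arg(dialect)
  family_level <- match.arg(family_level)
  lines <- readLines(path)
  if (dialect == "out") {
    body <- if (length(lines) > 3L) lines[-seq_len(3L)] else character()
    body_no <- seq_along(lines)[-seq_len(min(3L, length(lines)))]
    body_keep <- nzchar(trimws(body))
    body_no <- body_no[body_keep]
    body <- body[body_keep]
    fields <- strsplit(trimws(body), "[[:space:]]+")
    nf <- lengths(fields)
    if (any(nf < 11L)) {
      stop("unparsable RepeatMasker .out line ", body_no[which(nf < 11L)[1L]],
           " in ", path)
    }
    get <- function(i) vapply(fields, `[[`, "", i)
    chrom <- get(5L)
    start <- suppressWarnings(as.integer(get(6L)))
    end <- suppressWarnings(as.integer(get(7L)))
    if (anyNA(start) || anyNA(end)) {
      stop("non-numeric coordinates at RepeatMasker .out line ",
           body_no[which(is.na(start) | is.na(end))[1L]], " in ", path)
    }
    strand <- ifelse(get(9L) == "C", "-", "+")
    name <- get(10L)
    family <- get(11L)
  } else {
    df <- tryCatch(
      read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                 quote = "", comment.char = ""),
      error = function(e) stop("unparsable rmsk TSV '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    )
    need <- c("genoName", "genoStart", "genoEnd", "strand", "repName",
              "repClass", "repFamily")
    miss <- setdiff(need, names(df))
    if (length(miss)) {
      stop("rmsk TSV missing column(s): ", paste(miss, collapse = ", "))
    }
    chrom <- df$genoName
    start <- df$genoStart + 1L  # 0-based half-open -> 1-based closed
    end <- df$genoEnd
    strand <- df$strand
    name <- df$repName
    family <- ifelse(df$repFamily == df$repClass | df$repFamily == "",
                     df$repClass, paste(df$repClass, df$repFamily, sep = "/"))
  }
  if (family_level == "class") {
    family <- sub("/.*$", "", family)
  }
  cls <- sub("/.*$", "", family)
  keep <- !grepl("?", family, fixed = TRUE) &
    !(cls %in% c("Simple_repeat", "Low_complexity"))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom[keep],
    ranges = IRanges::IRanges(start = start[keep], end = end[keep]),
    strand = strand[keep]
  )
  gr$family <- family[keep]
  gr$name <- name[keep]
  gr
}

#' Repeat families present in an annotation
#' @param annotation a `GRanges` from [read_repeatmasker()].
#' @return sorted character vector of family labels.
#' @export
repeat_families <- function(annotation) sort(unique(annotation$family))

# Merged (reduced) instances of one family on one strand, so nested or
# overlapping entries are never double-counted.
.family_strand_merged <- function(annotation, family, strand) {
  sel <- annotation[annotation$family == family &
                      as.character(GenomicRanges::strand(annotation)) == strand]
  GenomicRanges::reduce(sel, ignore.strand = TRUE)
}

#' Bases of a region covered by a repeat family in one orientation
#'
#' Counts the bases of `region` covered by at least one instance of `family`
#' whose strand qualifies for `orientation` relative to `gene_strand`
#' ("sense": repeat strand equals the gene strand; "antisense": opposite).
#' Instances are merged per (family, strand) before counting.
#'
#' @param region a `GRanges` of disjoint intervals (e.g. one element of
#'   [exonic_region()]).
#' @param family repeat family label.
#' @param orientation `"sense"` or `"antisense"`.
#' @param gene_strand `"+"` or `"-"`.
#' @param annotation a `GRanges` from [read_repeatmasker()].
#' @return integer number of covered bases.
#' @export
family_overlap_bp <- function(region, family, orientation = c("sense", "antisense"),
                              gene_strand, annotation) {
  orientation <- match.arg(orientation)
  rep_strand <- if ((orientation == "sense") == (gene_strand == "+")) "+" else "-"
  merged <- .family_strand_merged(annotation, family, rep_strand)
  if (length(merged) == 0L || length(region) == 0L) return(0L)
  ov <- suppressWarnings(
    GenomicRanges::intersect(GenomicRanges::reduce(region, ignore.strand = TRUE),
                             merged, ignore.strand = TRUE))
  sum(GenomicRanges::width(ov))
}

# Overlap in bp between each gene's region set and a merged GRanges,
# vectorised over genes. regions: GRangesList named by gene_id.
.overlap_by_gene <- function(regions, merged) {
  out <- setNames(numeric(length(regions)), names(regions))
  if (length(merged) == 0L) return(out)
  flat <- unlist(regions, use.names = FALSE)
  if (length(flat) == 0L) return(out)
  gene_idx <- rep(seq_along(regions), lengths(regions))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(flat, merged, ignore.strand = TRUE))
  if (length(hits) == 0L) return(out)
  pw <- GenomicRanges::width(IRanges::pintersect(
    flat[S4Vectors::queryHits(hits)], merged[S4Vectors::subjectHits(hits)]
  ))
  agg <- rowsum(pw, group = gene_idx[S4Vectors::queryHits(hits)])
  out[as.integer(rownames(agg))] <- agg[, 1L]
  out
}

#' Per-gene repeat density table
#'
#' For every gene, repeat family, region (exon/intron) and orientation
#' (sense/antisense), computes the fraction of the region covered by merged
#' instances of the family on the qualifying strand. One record is emitted
#' for every present combination, including zero densities, so gene-set means
#' are well defined; genes with an empty intronic region emit no intron
#' records.
#'
#' @param gm a [GeneModels] object.
#' @param annotation a `GRanges` from [read_repeatmasker()].
#' @param families optional character vector of families (default: all
#'   families in `annotation`).
#' @return a `data.frame` with columns `gene_id`, `family`, `region`,
#'   `orientation`, `region_length`, `overlap_bp`, `density`.
#' @export
density_table <- function(gm, annotation, families = NULL) {
  if (is.null(families)) families <- repeat_families(annotation)
  ex_regions <- exonic_region(gm)
  in_regions <- intronic_region(gm)
  gene_strand <- as.character(GenomicRanges::strand(gm$genes))
  ex_len <- sum(GenomicRanges::width(ex_regions))
  in_len <- sum(GenomicRanges::width(in_regions))

  blocks <- list()
  for (family in families) {
    ov <- list()
    for (rep_strand in c("+", "-")) {
      merged <- .family_strand_merged(annotation, family, rep_strand)
      ov[[rep_strand]] <- list(
        exon = .overlap_by_gene(ex_regions, merged),
        intron = .overlap_by_gene(in_regions, merged)
      )
    }
    for (region in c("exon", "intron")) {
      len <- if (region == "exon") ex_len else in_len
      keep <- len > 0L
      if (!any(keep)) next
      plus <- ov[["+"]][[region]]
      minus <- ov[["-"]][[region]]
      sense_bp <- ifelse(gene_strand == "+", plus, minus)
      anti_bp <- ifelse(gene_strand == "+", minus, plus)
      for (orientation in c("sense", "antisense")) {
        bp <- if (orientation == "sense") sense_bp else anti_bp
        blocks[[length(blocks) + 1L]] <- data.frame(
          gene_id = names(gm$genes)[keep],
          family = family,
          region = region,
          orientation = orientation,
          region_length = as.integer(len[keep]),
          overlap_bp = as.integer(bp[keep]),
          density = as.numeric(bp[keep]) / len[keep],
          row.names = NULL, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, blocks)
  if (is.null(out)) {
    out <- data.frame(gene_id = character(), family = character(),
                      region = character(), orientation = character(),
                      region_length = integer(), overlap_bp = integer(),
                      density = numeric(), stringsAsFactors = FALSE)
  }
  out
}

#' Write a density table to TSV
#' @param densities a `data.frame` from [density_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_density_table <- function(densities, path) {
  write.table(densities, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
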