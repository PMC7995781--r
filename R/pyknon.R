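#' Read a motif (pyknon) list
#'
#' Reads a motif list as TSV with columns `motif_id` and `sequence`, or as a
#' plain list of one sequence per line (ids are then generated).
#'
#' @param path input file.
#' @return a `data.frame` with columns `motif_id`, `sequence` (uppercase).
#' @export
read_motifs <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) {
    df <- read.table(path, sep = "\t", header = grepl("motif_id", first),
                     stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("motif TSV needs motif_id and sequence columns")
    names(df)[1:2] <- c("motif_id", "sequence")
  } else {
    seqs <- read_gene_set(path)
    df <- data.frame(motif_id = sprintf("pyk%05d", seq_along(seqs)),
                     sequence = seqs, stringsAsFactors = FALSE)
  }
  df$sequence <- toupper(df$sequence)
  .validate_motifs(df)
  df[, c("motif_id", "sequence")]
}

.validate_motifs <- function(motifs) {
  if (anyDuplicated(motifs$motif_id)) stop("duplicated motif_id")
  bad <- !grepl("^[ACGT]+$", motifs$sequence)
  if (any(bad)) {
    stop("motif(s) with non-ACGT characters: ",
         paste(head(motifs$motif_id[bad], 5L), collapse = ", "))
  }
  invisible(motifs)
}

#' Exhaustive exact motif search
#'
#' Finds every exact occurrence of each motif in a set of sequences,
#' including overlapping occurrences, on the forward strand of the provided
#' sequences (optionally also reverse-complement matches). Ambiguous bases
#' (`N`) never match.
#'
#' @param motifs a `data.frame` with `motif_id` and `sequence` columns (see
#'   [read_motifs()]), or a character vector of sequences.
#' @param sequences a named character vector, a
#'   [Biostrings::DNAStringSet], or the path to a FASTA file.
#' @param both_strands also report reverse-complement matches (reported on
#'   strand `-`); default `FALSE`.
#' @return a `data.frame` with columns `motif_id`, `seqname`, `start`, `end`
#'   (1-based closed), `strand`.
#' @export
find_motif_hits <- function(motifs, sequences, both_strands = FALSE) {
  if (is.character(motifs)) {
    motifs <- data.frame(motif_id = sprintf("pyk%05d", seq_along(motifs)),
                         sequence = toupper(motifs), stringsAsFactors = FALSE)
  }
  .validate_motifs(motifs)
  subj <- .as_dnastringset(sequences)
  out <- vector("list", nrow(motifs) * 2L)
  k <- 0L
  for (i in seq_len(nrow(motifs))) {
    for (str in if (both_strands) c("+", "-") else "+") {
      pat <- motifs$sequence[i]
      if (str == "-") {
        pat <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pat)))
      }
      m <- Biostrings::vmatchPattern(pat, subj, fixed = TRUE)
      n_hits <- S4Vectors::elementNROWS(m)
      if (sum(n_hits) == 0L) next
      ir <- unlist(m)
      k <- k + 1L
      out[[k]] <- data.frame(
        motif_id = motifs$motif_id[i],
        seqname = rep(names(subj), n_hits),
        start = IRanges::start(ir),
        end = IRanges::end(ir),
        strand = str,
        row.names = NULL, stringsAsFactors = FALSE
      )
    }
  }
  res <- if (k) do.call(rbind, out[seq_len(k)]) else
    data.frame(motif_id = character(), seqname = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)
  res[order(res$motif_id, res$seqname, res$start), , drop = FALSE]
}

.as_dnastringset <- function(sequences) {
  if (inherits(sequences, "DNAStringSet")) return(sequences)
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences)) {
    return(Biostrings::readDNAStringSet(sequences))
  }
  if (is.character(sequences)) {
    if (is.null(names(sequences))) {
      names(sequences) <- sprintf("seq%d", seq_along(sequences))
    }
    return(Biostrings::DNAStringSet(toupper(sequences)))
  }
  stop("sequences must be a DNAStringSet, a FASTA path, or named strings")
}

#' Convert motif hits to GRanges
#' @param hits a hits `data.frame` from [find_motif_hits()].
#' @return a `GRanges` with a `motif_id` column.
#' @export
hits_as_granges <- function(hits) {
  gr <- GenomicRanges::GRanges(hits$seqname,
                               IRanges::IRanges(hits$start, hits$end),
                               strand = hits$strand)
  gr$motif_id <- hits$motif_id
  gr
}

#' Write motif hits as BED (0-based half-open)
#' @param hits a hits `data.frame` from [find_motif_hits()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(hits$seqname, hits$start - 1L, hits$end, hits$motif_id,
                    0L, hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Motifs with exonic hits, per gene
#'
#' Maps genomic motif hits to genes by overlap with the genes' exonic
#' regions.
#'
#' @param hits a hits `data.frame` from [find_motif_hits()] in genomic
#'   coordinates.
#' @param gm a [GeneModels] object.
#' @return a `data.frame` with columns `gene_id`, `motif_id` (distinct
#'   pairs), plus `n_instances` (hits of that motif overlapping that gene's
#'   exonic region).
#' @export
exonic_motif_table <- function(hits, gm) {
  if (nrow(hits) == 0L) {
    return(data.frame(gene_id = character(), motif_id = character(),
                      n_instances = integer(), stringsAsFactors = FALSE))
  }
  hgr <- hits_as_granges(hits)
  regions <- exonic_region(gm)
  flat <- unlist(regions, use.names = FALSE)
  gene_idx <- rep(seq_along(regions), lengths(regions))
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(hgr, flat, ignore.strand = TRUE))
  if (length(ov) == 0L) {
    return(data.frame(gene_id = character(), motif_id = character(),
                      n_instances = integer(), stringsAsFactors = FALSE))
  }
  df <- unique(data.frame(
    hit = S4Vectors::queryHits(ov),
    gene = gene_idx[S4Vectors::subjectHits(ov)]
  ))
  key <- data.frame(gene_id = names(regions)[df$gene],
                    motif_id = hgr$motif_id[df$hit],
                    stringsAsFactors = FALSE)
  agg <- aggregate(list(n_instances = rep(1L, nrow(key))),
                   by = key, FUN = sum)
  agg[order(agg$gene_id, agg$motif_id), , drop = FALSE]
}

#' Partition motifs across gene sets (Venn cells)
#'
#' For each named gene set, collects the distinct motifs with at least one
#' exonic hit in a gene of the set, then reports every Venn cell (membership
#' pattern) with its motif count. Gene ids in a set that are absent from the
#' exonic table produce a warning and are skipped.
#'
#' @param gene_sets a named list of character vectors of gene ids.
#' @param exonic_motifs a `data.frame` from [exonic_motif_table()].
#' @return a list with `per_set` (named list of motif-id vectors) and
#'   `cells` (a `data.frame` with columns `cell` -- set names joined by `&`,
#'   or `<set>_only` semantics encoded by the pattern -- and `n`, plus a
#'   `motifs` list-column).
#' @export
partition_motifs <- function(gene_sets, exonic_motifs) {
  if (is.null(names(gene_sets)) || any(!nzchar(names(gene_sets)))) {
    stop("gene_sets must be a named list")
  }
  known <- unique(exonic_motifs$gene_id)
  per_set <- lapply(names(gene_sets), function(nm) {
    ids <- unique(as.character(gene_sets[[nm]]))
    unknown <- setdiff(ids, known)
    if (length(unknown)) {
      warning(length(unknown), " gene id(s) in set '", nm,
              "' have no exonic motif record; skipped")
    }
    sort(unique(exonic_motifs$motif_id[exonic_motifs$gene_id %in% ids]))
  })
  names(per_set) <- names(gene_sets)

  all_motifs <- sort(unique(unlist(per_set)))
  member <- vapply(per_set, function(s) all_motifs %in% s,
                   logical(length(all_motifs)))
  if (length(all_motifs) == 1L) member <- matrix(member, nrow = 1L,
                                                 dimnames = list(NULL, names(per_set)))
  pattern <- apply(member, 1L, function(r)
    paste(names(per_set)[r], collapse = "&"))
  cells <- lapply(split(all_motifs, pattern), sort)
  data_cells <- data.frame(cell = names(cells),
                           n = lengths(cells),
                           row.names = NULL, stringsAsFactors = FALSE)
  data_cells$motifs <- unname(cells)
  list(per_set = per_set, cells = data_cells)
}

#' Motifs unique to one gene set
#' @param partition result of [partition_motifs()].
#' @param set_name the set whose exclusive motifs are wanted.
#' @return character vector of motif ids found only in that set.
#' @export
unique_motifs <- function(partition, set_name) {
  i <- which(partition$cells$cell == set_name)
  if (length(i) == 0L) return(character())
  partition$cells$motifs[[i]]
}

#' Per-gene pyknon density profile
#'
#' Counts, per gene, the distinct motifs (restricted to `motif_subset` if
#' given) and total motif instances within the gene's exonic region, and
#' normalises by exonic length: the primary density is distinct motifs per
#' 10,000 bp of exonic sequence; `density_alt` is instances per 1,000 bp.
#'
#' @param arch architecture table from [architecture()].
#' @param exonic_motifs a `data.frame` from [exonic_motif_table()].
#' @param motif_subset optional character vector restricting the motifs
#'   counted (e.g. the motifs unique to one gene set).
#' @param gene_ids optional character vector restricting the genes (default:
#'   all genes in `arch`).
#' @return a `data.frame` with columns `gene_id`, `exonic_length`,
#'   `distinct_motifs`, `instances`, `density` (distinct per 10 kb),
#'   `density_alt` (instances per 1 kb).
#' @export
gene_density_profile <- function(arch, exonic_motifs, motif_subset = NULL,
                                 gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- arch$gene_id
  a <- arch[match(gene_ids, arch$gene_id), , drop = FALSE]
  if (anyNA(a$gene_id)) stop("gene id(s) missing from the architecture table")
  em <- exonic_motifs
  if (!is.null(motif_subset)) {
    em <- em[em$motif_id %in% motif_subset, , drop = FALSE]
  }
  nd <- table(factor(em$gene_id, levels = gene_ids))
  ni <- tapply(em$n_instances, factor(em$gene_id, levels = gene_ids), sum)
  ni[is.na(ni)] <- 0L
  data.frame(
    gene_id = gene_ids,
    exonic_length = a$exonic_length,
    distinct_motifs = as.integer(nd),
    instances = as.integer(ni),
    density = as.integer(nd) / a$exonic_length * 1e4,
    density_alt = as.integer(ni) / a$exonic_length * 1e3,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Attribute motifs to repeat families
#'
#' A motif belongs to a repeat family if at least one of its genomic hits
#' overlaps (by at least 1 bp, either strand) an instance of that family.
#' One motif may belong to several families, so family percentages are
#' computed over motifs and may sum to more than 100.
#'
#' @param hits a hits `data.frame` from [find_motif_hits()] in genomic
#'   coordinates.
#' @param annotation a `GRanges` from [read_repeatmasker()].
#' @param motif_ids optional character vector of motifs to attribute
#'   (default: all motifs in `hits`; motifs without overlapping hits get an
#'   empty family set).
#' @return a list with `per_motif` (named list: motif id -> character vector
#'   of families) and `summary` (a `data.frame` with `family`, `n_motifs`,
#'   `percent`).
#' @export
attribute_to_families <- function(hits, annotation, motif_ids = NULL) {
  if (is.null(motif_ids)) motif_ids <- unique(hits$motif_id)
  per_motif <- setNames(vector("list", length(motif_ids)), motif_ids)
  for (m in motif_ids) per_motif[[m]] <- character()
  h <- hits[hits$motif_id %in% motif_ids, , drop = FALSE]
  if (nrow(h) > 0L && length(annotation) > 0L) {
    hgr <- hits_as_granges(h)
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(hgr, annotation, ignore.strand = TRUE))
    if (length(ov) > 0L) {
      pairs <- unique(data.frame(
        motif_id = hgr$motif_id[S4Vectors::queryHits(ov)],
        family = annotation$family[S4Vectors::subjectHits(ov)],
        stringsAsFactors = FALSE
      ))
      sp <- split(pairs$family, pairs$motif_id)
      for (m in names(sp)) per_motif[[m]] <- sort(unique(sp[[m]]))
    }
  }
  fams <- sort(unique(unlist(per_motif)))
  n_mot <- vapply(fams, function(f)
    sum(vapply(per_motif, function(s) f %in% s, TRUE)), 1L)
  summary <- data.frame(
    family = fams,
    n_motifs = as.integer(n_mot),
    percent = if (length(motif_ids)) 100 * n_mot / length(motif_ids) else numeric(length(fams)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  list(per_motif = per_motif, summary = summary)
}

#' Compare per-gene pyknon densities between two gene groups
#'
#' Two-sided Mann-Whitney U test on the per-gene density values of two
#' groups. Completely tied input (every value identical) yields p = 1 with a
#' warning.
#'
#' @param profiles_a,profiles_b `data.frame`s from [gene_density_profile()],
#'   or numeric density vectors.
#' @param measure column compared when data frames are given (default
#'   `"density"`).
#' @return list with `statistic` (U) and `p`.
#' @export
compare_density_groups <- function(profiles_a, profiles_b,
                                   measure = "density") {
  va <- if (is.numeric(profiles_a)) profiles_a else profiles_a[[measure]]
  vb <- if (is.numeric(profiles_b)) profiles_b else profiles_b[[measure]]
  if (length(va) == 0L || length(vb) == 0L) stop("both groups must be non-empty")
  if (length(unique(c(va, vb))) == 1L) {
    warning("all density values tied; p set to 1")
    return(list(statistic = length(va) * length(vb) / 2, p = 1))
  }
  wt <- suppressWarnings(wilcox.test(va, vb, alternative = "two.sided",
                                     exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p = unname(wt$p.value))
}

#' Compare repeat-family attribution distributions
#'
#' Chi-squared test comparing two vectors of per-family motif counts (e.g.
#' from two [attribute_to_families()] summaries). Families absent from one
#' side count as zero; families whose pooled expected count would be zero
#' are dropped.
#'
#' @param counts_a,counts_b named integer vectors of per-family counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
compare_family_distributions <- function(counts_a, counts_b) {
  if (sum(counts_a) == 0 || sum(counts_b) == 0) {
    stop("zero-total count vector")
  }
  fams <- union(names(counts_a), names(counts_b))
  if (is.null(fams)) {
    if (length(counts_a) != length(counts_b)) {
      stop("unnamed count vectors must have equal length")
    }
    fams <- as.character(seq_along(counts_a))
    names(counts_a) <- names(counts_b) <- fams
  }
  a <- setNames(numeric(length(fams)), fams)
  b <- a
  a[names(counts_a)] <- counts_a
  b[names(counts_b)] <- counts_b
  keep <- (a + b) > 0
  tab <- rbind(a[keep], b[keep])
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}
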