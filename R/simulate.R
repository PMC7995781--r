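# All generator randomness flows from one integer seed; each output draws
# from a named substream so individual fixtures are reproducible on their own.
.substream <- function(seed, name) {
  s <- as.numeric(seed) %% 2147483647
  for (ch in utf8ToInt(name)) s <- (s * 31 + ch) %% 2147483647
  as.integer(s)
}

#' Specification of a synthetic genome
#'
#' Describes gene groups (with exon-count and log-normal exon/intron length
#' distributions) and repeat families with per-(group, region, orientation)
#' target densities. Defaults emulate compact protein-coding genes: a mean
#' of 8 exons per gene, exon lengths with median ~150 bp and intron lengths
#' with median ~1.5 kb, and a SINE/Alu-like family at moderate intronic
#' density.
#'
#' @param n_genes total number of genes.
#' @param groups `data.frame` with columns `name` and `fraction` (fractions
#'   sum to 1) and optional per-group overrides `exon_count_mean`,
#'   `exon_meanlog`, `exon_sdlog`, `intron_meanlog`, `intron_sdlog`.
#' @param exon_count_mean mean exon count per gene (geometric count of
#'   additional exons beyond the first).
#' @param exon_meanlog,exon_sdlog log-normal exon length parameters (bp).
#' @param intron_meanlog,intron_sdlog log-normal intron length parameters.
#' @param repeats `data.frame` with columns `family`, `group`, `region`
#'   (`exon`/`intron`), `orientation` (`sense`/`antisense`), `density`
#'   (target coverage fraction in \[0, 0.9\]).
#' @param jitter_precision precision of the per-gene Beta jitter around each
#'   target density (larger = tighter; `Inf` disables jitter).
#' @param repeat_unit_len typical repeat instance length in bp.
#' @param n_chrom number of chromosomes genes are distributed over.
#' @param intergenic_gap gap between consecutive genes in bp.
#' @return a list of class `genome_spec`.
#' @export
genome_spec <- function(n_genes = 500,
                        groups = data.frame(name = "all", fraction = 1),
                        exon_count_mean = 8,
                        exon_meanlog = log(150), exon_sdlog = 0.6,
                        intron_meanlog = log(1500), intron_sdlog = 0.9,
                        repeats = data.frame(
                          family = "SINE/Alu", group = "all",
                          region = "intron", orientation = "sense",
                          density = 0.2),
                        jitter_precision = 60,
                        repeat_unit_len = 300,
                        n_chrom = 4,
                        intergenic_gap = 2000) {
  stopifnot(n_genes >= 1, abs(sum(groups$fraction) - 1) < 1e-8)
  if (!is.null(repeats) && nrow(repeats)) {
    stopifnot(all(repeats$density >= 0))
    if (any(repeats$density > 0.9)) {
      stop("unattainable repeat density (> 0.9)")
    }
    stopifnot(all(repeats$region %in% c("exon", "intron")),
              all(repeats$orientation %in% c("sense", "antisense")),
              all(repeats$group %in% groups$name))
  }
  defaults <- list(exon_count_mean = exon_count_mean,
                   exon_meanlog = exon_meanlog, exon_sdlog = exon_sdlog,
                   intron_meanlog = intron_meanlog, intron_sdlog = intron_sdlog)
  for (f in names(defaults)) {
    if (is.null(groups[[f]])) groups[[f]] <- defaults[[f]]
  }
  stopifnot(all(groups$exon_count_mean >= 1),
            all(groups$exon_sdlog > 0), all(groups$intron_sdlog > 0))
  structure(list(n_genes = n_genes, groups = groups, repeats = repeats,
                 jitter_precision = jitter_precision,
                 repeat_unit_len = repeat_unit_len,
                 n_chrom = n_chrom, intergenic_gap = intergenic_gap),
            class = "genome_spec")
}

# Non-overlapping placement of `target_bp` covered bases within the
# intervals of one region, chopped into units of <= unit_len with random
# gaps; no spill-over across interval boundaries.
.place_in_intervals <- function(starts, ends, density, unit_len) {
  out_s <- integer()
  out_e <- integer()
  for (i in seq_along(starts)) {
    w <- ends[i] - starts[i] + 1L
    b <- round(density * w)
    if (b <= 0L) next
    n_pieces <- max(1L, ceiling(b / unit_len))
    piece <- rep(b %/% n_pieces, n_pieces)
    extra <- b - sum(piece)
    if (extra > 0L) piece[seq_len(extra)] <- piece[seq_len(extra)] + 1L
    piece <- piece[piece > 0L]
    n_pieces <- length(piece)
    free <- w - b
    gaps <- if (free > 0L) {
      brk <- sort(runif(n_pieces, 0, 1))
      diff(c(0, brk, 1)) * free
    } else rep(0, n_pieces + 1L)
    gaps <- floor(gaps)
    pos <- starts[i]
    for (p in seq_len(n_pieces)) {
      pos <- pos + gaps[p]
      out_s <- c(out_s, pos)
      out_e <- c(out_e, pos + piece[p] - 1L)
      pos <- pos + piece[p]
    }
  }
  list(start = out_s, end = out_e)
}

#' Generate a synthetic genome with planted repeat densities
#'
#' Draws gene models from the per-group length distributions of a
#' [genome_spec()], lays them out over chromosomes, and places repeat
#' instances to realise each group's target density per (family, region,
#' orientation) stratum. Per gene, the target density is jittered with a
#' Beta distribution (mean = group target) so genes vary realistically;
#' placement is non-overlapping within a stratum and the realised group
#' mean density stays within a few percent of the target. Deterministic
#' given `seed`.
#'
#' @param spec a [genome_spec()].
#' @param seed integer seed.
#' @param sequence also generate random chromosome sequences (needed for
#'   motif planting; default `FALSE`).
#' @return a list of class `synthetic_genome`: `gm` ([GeneModels]),
#'   `repeats` (`GRanges` with `family`, `name`), `groups` (`data.frame`
#'   `gene_id`, `group`), `sequences` (`DNAStringSet` or `NULL`), `spec`,
#'   `seed`.
#' @export
simulate_genome <- function(spec, seed, sequence = FALSE) {
  stopifnot(inherits(spec, "genome_spec"))
  set.seed(.substream(seed, "genome"))
  g <- spec$groups
  n <- spec$n_genes

  counts <- floor(g$fraction * n)
  rem <- n - sum(counts)
  if (rem > 0) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  group_of <- rep(g$name, counts)

  gene_id <- sprintf("g%05d", seq_len(n))
  chrom_of <- sprintf("chr%d", rep_len(seq_len(spec$n_chrom), n))
  strand_of <- sample(c("+", "-"), n, replace = TRUE)

  exon_rows <- vector("list", n)
  cursor <- setNames(rep(1L, spec$n_chrom), sprintf("chr%d", seq_len(spec$n_chrom)))
  for (i in seq_len(n)) {
    gi <- match(group_of[i], g$name)
    n_ex <- 1L + rgeom(1L, prob = 1 / g$exon_count_mean[gi])
    ex_len <- pmax(20L, round(rlnorm(n_ex, g$exon_meanlog[gi], g$exon_sdlog[gi])))
    in_len <- if (n_ex > 1L) {
      pmax(50L, round(rlnorm(n_ex - 1L, g$intron_meanlog[gi], g$intron_sdlog[gi])))
    } else integer()
    start <- cursor[chrom_of[i]]
    s <- integer(n_ex)
    e <- integer(n_ex)
    pos <- start
    for (k in seq_len(n_ex)) {
      s[k] <- pos
      e[k] <- pos + ex_len[k] - 1L
      pos <- e[k] + 1L + if (k < n_ex) in_len[k] else 0L
    }
    cursor[chrom_of[i]] <- e[n_ex] + spec$intergenic_gap
    exon_rows[[i]] <- data.frame(gene_id = gene_id[i], chrom = chrom_of[i],
                                 start = s, end = e, strand = strand_of[i],
                                 stringsAsFactors = FALSE)
  }
  gm <- GeneModels(do.call(rbind, exon_rows))

  rep_s <- integer(); rep_e <- integer(); rep_chr <- character()
  rep_str <- character(); rep_fam <- character()
  if (!is.null(spec$repeats) && nrow(spec$repeats)) {
    ex_regions <- exonic_region(gm)
    in_regions <- intronic_region(gm)
    set.seed(.substream(seed, "repeats"))
    for (r in seq_len(nrow(spec$repeats))) {
      rr <- spec$repeats[r, ]
      if (rr$density <= 0) next
      idx <- which(group_of == rr$group)
      for (i in idx) {
        reg <- if (rr$region == "exon") ex_regions[[i]] else in_regions[[i]]
        if (length(reg) == 0L) next
        d <- if (is.finite(spec$jitter_precision)) {
          rbeta(1L, rr$density * spec$jitter_precision,
                (1 - rr$density) * spec$jitter_precision)
        } else rr$density
        pl <- .place_in_intervals(GenomicRanges::start(reg),
                                  GenomicRanges::end(reg),
                                  d, spec$repeat_unit_len)
        if (length(pl$start) == 0L) next
        inst_strand <- if ((rr$orientation == "sense") == (strand_of[i] == "+"))
          "+" else "-"
        rep_s <- c(rep_s, pl$start)
        rep_e <- c(rep_e, pl$end)
        rep_chr <- c(rep_chr, rep(chrom_of[i], length(pl$start)))
        rep_str <- c(rep_str, rep(inst_strand, length(pl$start)))
        rep_fam <- c(rep_fam, rep(rr$family, length(pl$start)))
      }
    }
  }
  repeats <- GenomicRanges::GRanges(
    seqnames = rep_chr, ranges = IRanges::IRanges(rep_s, rep_e),
    strand = rep_str)
  repeats$family <- rep_fam
  repeats$name <- if (length(repeats)) {
    paste0(sub(".*/", "", rep_fam), "_", seq_along(repeats))
  } else character()

  sequences <- NULL
  if (sequence) {
    set.seed(.substream(seed, "sequence"))
    chrom_len <- cursor + 1000L
    sequences <- Biostrings::DNAStringSet(vapply(
      names(chrom_len),
      function(cn) paste(sample(c("A", "C", "G", "T"), chrom_len[cn],
                                replace = TRUE), collapse = ""),
      ""))
  }

  structure(list(gm = gm, repeats = repeats,
                 groups = data.frame(gene_id = gene_id, group = group_of,
                                     stringsAsFactors = FALSE),
                 sequences = sequences, spec = spec, seed = seed),
            class = "synthetic_genome")
}

#' Write synthetic-genome files
#'
#' Writes the GTF (gene + exon features, `gene_biotype "protein_coding"`),
#' a UCSC rmsk-style repeat TSV (0-based half-open), the group membership
#' TSV, and -- when sequences were generated -- a FASTA, so that every file
#' reader of the package can be exercised against known truth.
#'
#' @param sim a `synthetic_genome` from [simulate_genome()].
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths, invisibly.
#' @export
write_genome_files <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm <- sim$gm
  gtf <- file.path(dir, "genes.gtf")
  con <- file(gtf, "w")
  on.exit(close(con))
  for (i in seq_along(gm$genes)) {
    gid <- names(gm$genes)[i]
    attrs <- sprintf('gene_id "%s"; gene_biotype "protein_coding";', gid)
    span <- gm$genes[i]
    writeLines(sprintf("%s\tarchrep\tgene\t%d\t%d\t.\t%s\t.\t%s",
                       as.character(GenomicRanges::seqnames(span)),
                       GenomicRanges::start(span), GenomicRanges::end(span),
                       as.character(GenomicRanges::strand(span)), attrs), con)
    ex <- gm$exons[[i]]
    writeLines(sprintf("%s\tarchrep\texon\t%d\t%d\t.\t%s\t.\t%s",
                       as.character(GenomicRanges::seqnames(ex)),
                       GenomicRanges::start(ex), GenomicRanges::end(ex),
                       as.character(GenomicRanges::strand(ex)), attrs), con)
  }
  close(con)
  on.exit()

  rmsk <- file.path(dir, "repeats.tsv")
  fam <- sim$repeats$family
  cls <- sub("/.*$", "", fam)
  subfam <- ifelse(grepl("/", fam), sub("^[^/]*/", "", fam), cls)
  write.table(
    data.frame(genoName = as.character(GenomicRanges::seqnames(sim$repeats)),
               genoStart = GenomicRanges::start(sim$repeats) - 1L,
               genoEnd = GenomicRanges::end(sim$repeats),
               strand = as.character(GenomicRanges::strand(sim$repeats)),
               repName = sim$repeats$name, repClass = cls,
               repFamily = subfam, stringsAsFactors = FALSE),
    rmsk, sep = "\t", quote = FALSE, row.names = FALSE)

  groups <- file.path(dir, "groups.tsv")
  write.table(sim$groups, groups, sep = "\t", quote = FALSE, row.names = FALSE)

  paths <- c(gtf = gtf, rmsk = rmsk, groups = groups)
  if (!is.null(sim$sequences)) {
    fasta <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(sim$sequences, fasta, width = 80L)
    paths <- c(paths, fasta = fasta)
  }
  invisible(paths)
}

#' Specification of a synthetic expression cohort
#'
#' @param n_genes total genes.
#' @param tissues tissue (group) names.
#' @param samples_per_tissue samples per tissue.
#' @param markers_per_tissue planted marker genes per tissue (disjoint
#'   across tissues).
#' @param marker_fold fold elevation of a marker in its own tissue.
#' @param marker_baseline baseline abundance of marker genes outside their
#'   tissue.
#' @param baseline_meanlog,baseline_sdlog log-normal baseline abundance
#'   parameters for non-marker genes.
#' @param noise_sdlog log-normal multiplicative noise sigma (> 0).
#' @return a list of class `expression_spec`.
#' @export
expression_spec <- function(n_genes = 500, tissues = c("T1", "T2", "T3"),
                            samples_per_tissue = 20, markers_per_tissue = 10,
                            marker_fold = 40, marker_baseline = 1,
                            baseline_meanlog = log(10), baseline_sdlog = 1,
                            noise_sdlog = 0.4) {
  stopifnot(noise_sdlog > 0, marker_fold > 1,
            markers_per_tissue * length(tissues) <= n_genes)
  structure(list(n_genes = n_genes, tissues = tissues,
                 samples_per_tissue = samples_per_tissue,
                 markers_per_tissue = markers_per_tissue,
                 marker_fold = marker_fold, marker_baseline = marker_baseline,
                 baseline_meanlog = baseline_meanlog,
                 baseline_sdlog = baseline_sdlog, noise_sdlog = noise_sdlog),
            class = "expression_spec")
}

#' Generate a synthetic expression cohort with planted markers
#'
#' Non-marker genes get a log-normal baseline abundance shared across
#' tissues; each tissue receives a disjoint block of marker genes elevated
#' `marker_fold`-fold over their (low) baseline only in that tissue.
#' Log-normal multiplicative noise is applied per cell. Deterministic given
#' `seed`.
#'
#' @param spec an [expression_spec()].
#' @param seed integer seed.
#' @return list of class `synthetic_expression`: `matrix` (genes x
#'   samples), `labels` (named character vector), `truth` (`data.frame`
#'   `gene_id`, `role`, `tissue`), `spec`, `seed`.
#' @export
simulate_expression <- function(spec, seed) {
  stopifnot(inherits(spec, "expression_spec"))
  set.seed(.substream(seed, "expression"))
  n <- spec$n_genes
  gene_id <- sprintf("g%05d", seq_len(n))
  n_t <- length(spec$tissues)
  samples <- paste0(rep(spec$tissues, each = spec$samples_per_tissue), "_s",
                    rep(seq_len(spec$samples_per_tissue), times = n_t))
  labels <- setNames(rep(spec$tissues, each = spec$samples_per_tissue), samples)

  n_mark <- spec$markers_per_tissue * n_t
  marker_tissue <- rep(spec$tissues, each = spec$markers_per_tissue)
  base <- c(rep(spec$marker_baseline, n_mark),
            rlnorm(n - n_mark, spec$baseline_meanlog, spec$baseline_sdlog))
  mu <- matrix(base, nrow = n, ncol = length(samples),
               dimnames = list(gene_id, samples))
  for (i in seq_len(n_mark)) {
    mu[i, labels == marker_tissue[i]] <-
      mu[i, labels == marker_tissue[i]] * spec$marker_fold
  }
  noise <- matrix(rlnorm(n * length(samples), 0, spec$noise_sdlog),
                  nrow = n)
  truth <- data.frame(
    gene_id = gene_id,
    role = c(rep("marker", n_mark), rep("background", n - n_mark)),
    tissue = c(marker_tissue, rep(NA_character_, n - n_mark)),
    stringsAsFactors = FALSE)
  structure(list(matrix = mu * noise, labels = labels, truth = truth,
                 spec = spec, seed = seed),
            class = "synthetic_expression")
}

#' Generate synthetic binarized tissue profiles
#'
#' Directly emulates a binarized cohort: each tissue has a disjoint block of
#' marker genes expressed (`TRUE`) only in that tissue; all other genes are
#' expressed independently with probability `background_prob`. Each bit is
#' then flipped with probability `flip_prob` (label-independent noise).
#'
#' @param n_genes,tissues,samples_per_tissue,markers_per_tissue cohort shape.
#' @param background_prob expression probability of non-marker genes.
#' @param flip_prob bit-flip noise probability.
#' @param seed integer seed.
#' @return list: `binary` (logical genes x samples), `labels`, `markers`
#'   (`data.frame` `gene_id`, `tissue`).
#' @export
simulate_binary_profiles <- function(n_genes = 500,
                                     tissues = c("T1", "T2", "T3"),
                                     samples_per_tissue = 60,
                                     markers_per_tissue = 10,
                                     background_prob = 0.5,
                                     flip_prob = 0.05, seed = 1) {
  set.seed(.substream(seed, "binary"))
  n_t <- length(tissues)
  gene_id <- sprintf("g%05d", seq_len(n_genes))
  samples <- paste0(rep(tissues, each = samples_per_tissue), "_s",
                    rep(seq_len(samples_per_tissue), times = n_t))
  labels <- setNames(rep(tissues, each = samples_per_tissue), samples)
  n_mark <- markers_per_tissue * n_t
  marker_tissue <- rep(tissues, each = markers_per_tissue)

  b <- matrix(runif(n_genes * length(samples)) < background_prob,
              nrow = n_genes, dimnames = list(gene_id, samples))
  for (i in seq_len(n_mark)) {
    b[i, ] <- labels == marker_tissue[i]
  }
  flip <- matrix(runif(n_genes * length(samples)) < flip_prob, nrow = n_genes)
  b <- xor(b, flip)
  list(binary = b, labels = labels,
       markers = data.frame(gene_id = gene_id[seq_len(n_mark)],
                            tissue = marker_tissue, stringsAsFactors = FALSE))
}

#' Plant motifs into a synthetic genome
#'
#' Generates random motifs and plants each one at a random exonic position;
#' a chosen fraction additionally gets a copy inside an instance of a given
#' repeat family. Planted positions never overlap each other. The genome's
#' sequences are edited in place, so an exhaustive search recovers at least
#' the planted occurrences, and family attribution recovers the planted
#' family memberships.
#'
#' @param sim a `synthetic_genome` with sequences
#'   (`simulate_genome(..., sequence = TRUE)`).
#' @param n_motifs number of motifs.
#' @param len_range motif length range in bp (min >= 6).
#' @param family_fraction named numeric vector: fraction of motifs also
#'   planted inside each repeat family (e.g. `c("SINE/Alu" = 0.5)`); may be
#'   `NULL`.
#' @param unplaced_fraction fraction of motifs generated but not planted
#'   anywhere (zero-hit controls).
#' @param seed integer seed.
#' @return list: `motifs` (`data.frame` `motif_id`, `sequence`), `genome`
#'   (the edited `synthetic_genome`), `truth` (`data.frame` `motif_id`,
#'   `exon_gene`, `family`).
#' @export
simulate_motifs <- function(sim, n_motifs = 30, len_range = c(12, 16),
                            family_fraction = c("SINE/Alu" = 0.5),
                            unplaced_fraction = 0.1, seed = 1) {
  stopifnot(inherits(sim, "synthetic_genome"))
  if (is.null(sim$sequences)) {
    stop("genome was generated without sequences; rerun simulate_genome(",
         "sequence = TRUE)")
  }
  stopifnot(len_range[1L] >= 6L)
  set.seed(.substream(seed, "motifs"))
  lens <- sample(seq(len_range[1L], len_range[2L]), n_motifs, replace = TRUE)
  motifs <- data.frame(
    motif_id = sprintf("pyk%05d", seq_len(n_motifs)),
    sequence = vapply(lens, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      ""),
    stringsAsFactors = FALSE)

  used <- list()  # per chromosome: matrix of reserved [start, end]
  reserve <- function(chrom, start, end) {
    u <- used[[chrom]]
    if (!is.null(u) && any(start <= u[, 2L] & end >= u[, 1L])) return(FALSE)
    used[[chrom]] <<- rbind(u, c(start, end))
    TRUE
  }
  seqs <- as.character(sim$sequences)
  plant <- function(chrom, start, motif_seq) {
    end <- start + nchar(motif_seq) - 1L
    if (!reserve(chrom, start, end)) return(FALSE)
    substr(seqs[[chrom]], start, end) <<- motif_seq
    TRUE
  }

  n_unplaced <- floor(unplaced_fraction * n_motifs)
  placed_idx <- seq_len(n_motifs - n_unplaced)
  exons_flat <- unlist(sim$gm$exons)
  truth <- data.frame(motif_id = motifs$motif_id,
                      exon_gene = NA_character_, family = NA_character_,
                      stringsAsFactors = FALSE)

  for (i in placed_idx) {
    L <- nchar(motifs$sequence[i])
    ok <- FALSE
    for (try in seq_len(50L)) {
      cand <- exons_flat[GenomicRanges::width(exons_flat) >= L]
      if (length(cand) == 0L) break
      e <- cand[sample.int(length(cand), 1L)]
      off <- sample.int(GenomicRanges::width(e) - L + 1L, 1L) - 1L
      chrom <- as.character(GenomicRanges::seqnames(e))
      if (plant(chrom, GenomicRanges::start(e) + off, motifs$sequence[i])) {
        truth$exon_gene[i] <- names(e)
        ok <- TRUE
        break
      }
    }
    if (!ok) warning("could not plant motif ", motifs$motif_id[i],
                     " in an exon")
  }

  for (fam in names(family_fraction)) {
    n_fam <- floor(family_fraction[[fam]] * n_motifs)
    if (n_fam == 0L) next
    targets <- placed_idx[seq_len(min(n_fam, length(placed_idx)))]
    inst <- sim$repeats[sim$repeats$family == fam]
    for (i in targets) {
      L <- nchar(motifs$sequence[i])
      cand <- inst[GenomicRanges::width(inst) >= L]
      if (length(cand) == 0L) {
        warning("no ", fam, " instance large enough for motif ",
                motifs$motif_id[i])
        next
      }
      for (try in seq_len(50L)) {
        r <- cand[sample.int(length(cand), 1L)]
        off <- sample.int(GenomicRanges::width(r) - L + 1L, 1L) - 1L
        chrom <- as.character(GenomicRanges::seqnames(r))
        if (plant(chrom, GenomicRanges::start(r) + off, motifs$sequence[i])) {
          truth$family[i] <- fam
          break
        }
      }
    }
  }

  genome <- sim
  genome$sequences <- Biostrings::DNAStringSet(seqs)
  names(genome$sequences) <- names(sim$sequences)
  list(motifs = motifs, genome = genome, truth = truth)
}
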