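# Shared fixture builders and independent oracles.

make_gm <- function(...) {
  GeneModels(data.frame(..., stringsAsFactors = FALSE))
}

# Per-base boolean-mask oracle for one gene: recomputes exonic/intronic
# lengths and region boundaries position by position, independent of the
# interval arithmetic under test.
mask_oracle <- function(span_start, span_end, exon_starts, exon_ends) {
  offset <- span_start - 1L
  mask <- logical(span_end - offset)
  for (i in seq_along(exon_starts)) {
    mask[(exon_starts[i] - offset):(exon_ends[i] - offset)] <- TRUE
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths) + offset
  starts <- ends - r$lengths + 1L
  list(
    exonic_length = sum(mask),
    intronic_length = sum(!mask),
    exon_starts = starts[r$values], exon_ends = ends[r$values],
    intron_starts = starts[!r$values], intron_ends = ends[!r$values]
  )
}

# Per-base oracle for covered bases of [starts, ends] intervals by a set of
# (possibly overlapping) repeat intervals.
overlap_oracle <- function(reg_starts, reg_ends, rep_starts, rep_ends) {
  if (length(reg_starts) == 0L) return(0L)
  lo <- min(reg_starts)
  hi <- max(reg_ends)
  reg <- logical(hi - lo + 1L)
  for (i in seq_along(reg_starts)) {
    reg[(reg_starts[i] - lo + 1L):(reg_ends[i] - lo + 1L)] <- TRUE
  }
  cov <- logical(hi - lo + 1L)
  for (i in seq_along(rep_starts)) {
    s <- max(rep_starts[i], lo)
    e <- min(rep_ends[i], hi)
    if (s <= e) cov[(s - lo + 1L):(e - lo + 1L)] <- TRUE
  }
  sum(reg & cov)
}

# Naive position-by-position exact-match oracle (overlapping occurrences
# included), independent of the Biostrings-based search.
naive_motif_hits <- function(motif, seq) {
  s <- charToRaw(seq)
  m <- charToRaw(motif)
  L <- length(m)
  if (length(s) < L) return(integer())
  cand <- which(s == m[1L])
  cand <- cand[cand <= length(s) - L + 1L]
  for (j in seq_len(L - 1L)) {
    if (length(cand) == 0L) break
    cand <- cand[s[cand + j] == m[j + 1L]]
  }
  cand
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A random single-gene model with span <= max_span, plus its oracle.
random_gene <- function(id, max_span = 1e5) {
  n_ex <- sample(1:12, 1L)
  span_start <- sample(1:1000, 1L)
  pos <- span_start
  s <- integer(n_ex); e <- integer(n_ex)
  for (k in seq_len(n_ex)) {
    s[k] <- pos
    e[k] <- pos + sample(20:800, 1L) - 1L
    pos <- e[k] + sample(1:3000, 1L)
  }
  # keep within max_span
  keep <- e - span_start + 1L <= max_span
  s <- s[keep]; e <- e[keep]
  data.frame(gene_id = id, chrom = "chr1", start = s, end = e, strand = "+",
             stringsAsFactors = FALSE)
}

rm_out_fixture <- function() {
  c(
    "   SW   perc perc perc  query     position in query            matching          repeat              position in repeat",
    "score   div. del. ins.  sequence  begin    end          (left) repeat            class/family      begin  end    (left)   ID",
    "",
    "  463   1.3  0.6  1.7  chr1        1001    1300  (248955000) + AluY              SINE/Alu              1   300    (12)   1",
    "  239  29.4  1.9  1.0  chr1        2001    2400  (248954000) C L1M5              LINE/L1             (0)   400   5000    2",
    "  100   5.0  0.0  0.0  chr1        3001    3100  (248953000) + MER5              DNA?                  1   100     (0)   3",
    "   50   2.0  0.0  0.0  chr1        4001    4050  (248952000) + (TA)n             Simple_repeat         1    50     (0)   4"
  )
}
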