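---
title: "archrep: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{archrep: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`archrep` asks a structural question about differential gene expression:
do the genes that change expression in a comparison differ *architecturally*
— in exon and intron length, in compactness, in their repetitive-element
content — from the genes that do not? The package implements the complete
analysis chain for that question: gene architecture from annotation, per-gene
repeat density, a Monte Carlo enrichment framework, cumulative-distribution
length-bias curves, pyknon (k-mer motif) analysis, rank-based cross-platform
differential analysis, and binarized-expression tissue signatures. This
vignette records the models, parameter choices and numerical decisions; the
README shows a worked example.

## Gene architecture

A gene is its genomic span plus a set of exon intervals. Three derived
quantities drive everything downstream:

* **exonic region** — the union of all exons (overlapping and adjacent exons
  merged); its total length is the **exonic length**;
* **intronic region** — the span minus the exonic region; its length is the
  **intronic length**, and exonic + intronic length always equals the span;
* **exonic content** — exonic length divided by span length, a compactness
  measure in (0, 1]. A large gene with few short exons (hexokinase-like:
  ~132 kb span, ~4.5 kb of exon) has content ≈ 0.03; a single-exon gene has
  content 1.

When a gene has several transcripts, the gene-level exon set is the union of
all transcript exons. That is the only reading under which "union of its
exons" is well defined without choosing a canonical transcript, and it makes
exonic content independent of isoform annotation depth. Genes whose exons
span multiple chromosomes or strands are rejected with an error naming the
gene; they cannot carry a single span. By default only
`gene_biotype == "protein_coding"` entries are read from the GTF.

**Coordinates.** Internally every interval is a `GRanges` (1-based, closed)
— the native convention of the Bioconductor interval stack this package is
built on, so no interval arithmetic is hand-written here. GTF input is
already 1-based closed; UCSC rmsk tables (0-based half-open) are shifted on
read; BED output is shifted on write. Keeping a single internal convention
and isolating conversions in the readers/writers is the point; which
convention it is matters less.

## Repeat density

Repeat instances come from RepeatMasker output (native `.out` or UCSC
rmsk-style TSV). Following standard practice, low-confidence families (label
containing `?`) and the `Simple_repeat` and `Low_complexity` classes are
dropped on read. The working family label is `repClass/repFamily` (e.g.
`SINE/Alu`, `LINE/L1`); a class-only mode is available.

The density of family *X* in a region of a gene is the fraction of the
region's bases covered by at least one instance of *X* on the qualifying
strand. Two decisions here:

* **Merging.** Instances are merged (reduced) per family and strand before
  counting, so nested and overlapping RepeatMasker entries are never double
  counted and density is a true coverage fraction in [0, 1].
* **Orientation.** "Sense" means the repeat strand equals the gene strand,
  "antisense" the opposite. Densities are computed separately for
  exon/intron × sense/antisense, giving four strata per family per gene.
  Flipping every repeat strand swaps the sense and antisense columns exactly
  (a property test enforces this).

Genes with an empty intronic region emit no intron records; all other
combinations are emitted explicitly, including zeros, so gene-set means are
well defined.

## Monte Carlo enrichment

To ask whether a gene set is enriched or depleted for family *X* in a
stratum, the observed statistic is the set's mean density. The null is built
by resampling: in each of `iterations` (default 10,000) iterations, `|set|`
genes are drawn **without replacement** from the background and their mean
density recorded — one shared gene resample per iteration across all strata,
so the family-level nulls are computed on the same random sets. The Z-score
is the observed mean standardized by the null mean and SD; positive Z means
more density than expected by chance (enrichment), negative depletion.
A two-sided empirical p-value (smaller tail of the null, doubled, with the
usual +1 correction) accompanies each Z, and a two-sample Kolmogorov-Smirnov
test of the per-gene density distributions (set vs background) is reported
alongside, since a mean shift and a distribution shift are different
statements. The empirical p-values are corrected by Benjamini-Hochberg
jointly across all strata of one comparison, and a stratum is called
significant when `|Z| >= 2` **and** FDR ≤ 5% (both thresholds
configurable).

Strata with zero null SD (e.g. a family entirely absent from a region type)
are flagged non-evaluable: Z is undefined there, and they are excluded from
the FDR correction rather than polluting it with meaningless p-values.
Sampling without replacement is chosen because the background is a finite
gene universe and the target is one of its subsets; it also fixes the null
variance given the seed, making runs bit-reproducible.

The heatmap matrix view keeps only families with at least one cell at
`|Z| >= 2`, the conventional display filter for such enrichment tables.

Calibration: for a random null target, Z is approximately standard normal,
so the expected rate of `|Z| >= 2` is the two-sided normal tail ≈ 0.0455.
The acceptance suite measures this rate over 500 random targets (200 of
2,000 synthetic genes, 1,000 iterations each) and requires it to fall in
[0.025, 0.07].

## Length-bias curves

For a measure (exonic length, intronic length, or exonic content) the curve
is `delta(x) = F_background(x) − F_set(x)` evaluated on the pooled sorted
unique values — exact empirical CDFs, no binning. The sign is chosen so that
a set shifted towards *larger* values plots *above* zero ("positive =
longer"). The maximum of `|delta|` is by construction the two-sample KS
statistic, which is the package's invariant linking the display to the
test. A 3-point moving average (shrinking to the available points at the
boundaries) is provided for display only; statistics are always computed on
the unsmoothed curve. KS p-values are exact for tie-free samples up to
n = 50 per side and asymptotic otherwise. Genes without introns are dropped
from intronic-length comparisons (the quantity is undefined for them), and
set and background medians are recorded for annotation.

## Pyknons

Pyknon motifs are *inputs* (one sequence per line, or `motif_id`/`sequence`
TSV); the package searches them exhaustively — every exact occurrence,
overlapping occurrences included, `N` never matches — using
`Biostrings::vmatchPattern` (the test suite checks it base-by-base against a
naive sliding-window oracle). Search is on the forward strand of the
provided sequence by default, because pyknons are genome-strand-defined
motifs; `both_strands = TRUE` adds reverse-complement matches.

Downstream operations:

* **Partition** — for named gene sets, the distinct motifs with ≥ 1 exonic
  hit per set, and every Venn cell; cell sizes sum to the number of distinct
  motifs in the union (conservation is tested).
* **Per-gene profile** — the primary density is *distinct motifs per
  10,000 bp of exonic length*; *instances per 1,000 bp* is emitted in
  parallel as `density_alt`. Both normalisations are defensible and they
  answer slightly different questions (motif diversity vs motif load), so
  the package computes both rather than privileging one.
* **Family attribution** — a motif belongs to a repeat family if ≥ 1 bp of
  at least one of its genomic hits overlaps an instance, either strand. One
  motif can belong to several families, so family percentages are computed
  over motifs and may sum past 100%.
* **Statistics** — per-gene densities of two sets are compared with a
  two-sided Mann-Whitney U test; family count distributions with a
  chi-squared test (families with zero pooled counts dropped).

## Differential expression stand-ins

The package's expression layer provides the filters (remove the bottom 25%
by mean, keep the top 50%, keep mean > 2 RPKM — all with floor counts and
gene-id tie-breaks so output is deterministic), twofold-change calling with
a 0.1 pseudo-count for zero means, and a permutation test used where a
dedicated differential-abundance method would otherwise be:

`d = (mean(B) − mean(A)) / (se + s0)`, with `se` the pooled standard error
and `s0` the median of all per-gene `se` values — a variance-stabilising
offset that stops near-constant genes from dominating. Group labels are
permuted (exhaustively when the number of distinct assignments does not
exceed `n_perm`, otherwise `n_perm` random draws), each gene's two-sided
p-value is the fraction of its own permuted `|d|` values reaching the
observed one, and BH-FDR splits significant genes into up/down sets.

**Power and granularity.** A per-gene permutation p-value cannot go below
2/(number of distinct assignments): with 5 vs 5 samples (252 assignments)
the floor is 0.0079, which BH at 5% over hundreds of genes cannot clear
unless a large fraction of genes is differential. The test fixtures
therefore use 6 vs 6 (924 assignments, floor 0.0022) for FDR 5% checks and
12 vs 12 with 5,000 sampled permutations for the FDR 1% rank analysis —
at smaller sample sizes a permutation test at those FDR levels is simply
underpowered, which is a property of the method, not of the implementation.
For abundance data spanning orders of magnitude, run the test on
`log2(x + 1)` values; the raw-difference statistic otherwise underweights
low-abundance genes.

**Rank analysis.** For cross-platform comparisons, each sample is
rank-normalized (rank 1 = highest expression, ties averaged), which is
invariant to any per-sample monotone transform of the raw values. The same
permutation machinery then runs on ranks (default FDR 1%); in its output,
"up" means better (numerically smaller) rank — higher abundance — in the
second cohort. Set overlaps are scored with the one-sided hypergeometric
upper tail.

## Binarized tissue signatures

Per sample, genes above 2 (FPKM-like units) are candidates and the top 50%
of candidates by abundance are "expressed"; `k` is rounded half up for odd
candidate counts, and ties break by abundance then gene id, so binarization
is deterministic and invariant to per-sample monotone transforms above the
threshold. Two gene filters precede learning:

* **widely expressed** — expressed in > 90% of samples within *every*
  tissue; these cannot be tissue-specific and are excluded;
* **uninformative** — the literal rule removes genes not-expressed in
  < 50% of samples within every tissue. Taken literally this subsumes the
  widely-expressed rule (any widely expressed gene also fails it); the two
  rules are kept as separate, independently reported steps, and a stricter
  `rule = "any_tissue"` variant is available. The conflict is inherent to
  the two definitions and is documented rather than silently resolved.

Classification is one-vs-one: one linear SVM (`e1071::svm`, `C = 1`,
unscaled 0/1 features) per tissue pair, a sample's tissue probability is its
share of pairwise votes (`votes / (n_tissues − 1)`), and a sample whose top
probability is *strictly below* 0.5 goes to the rejection class "Other"
(probability exactly 0.5 is still assigned — the rule is "lower than").
Cross-validation is stratified by tissue (10 folds by default, seeded), and
the confusion matrix reports row percentages averaged over folds. The
variable importance of a gene is the mean of its squared weights across all
pairwise models; on synthetic cohorts with disjoint planted markers, all
markers outrank all background genes by VI.

## Synthetic data

The generator exists so that every stage has a ground truth. It emulates:

* **gene models** — per-group geometric exon counts (default mean 8) and
  log-normal exon/intron lengths (defaults: exon median 150 bp, sdlog 0.6;
  intron median 1.5 kb, sdlog 0.9 — compact-protein-coding-gene territory);
* **repeats** — per (group × family × region × orientation) target
  coverage; each gene's realised target is Beta-jittered (precision 60)
  around the group mean so genes vary realistically, then instances
  (~300 bp units) are placed without overlap within the region, never
  spilling across exon/intron boundaries, so stratum densities stay
  independently controllable. Realised group means land within a few
  percent of target (tested at ±10%);
* **sequence and motifs** — random chromosomes consistent with the
  coordinates; motifs are planted at reserved, non-overlapping positions in
  exons and/or inside chosen repeat-family instances, with a truth table of
  intended placements;
* **expression** — log-normal baselines with disjoint per-tissue marker
  blocks elevated by a configurable fold (default 40, chosen so markers
  clear the binarization threshold and top-50% cut in their own tissue),
  log-normal multiplicative noise; plus a direct binary-profile generator
  (markers on in their tissue, background Bernoulli 0.5, optional bit-flip
  noise) for classifier studies.

All randomness flows from a single integer seed through named substreams
(one per output), so each artifact is individually reproducible and whole
runs are bit-identical under a fixed seed.

What the generator does **not** emulate: real base composition, GC and
repeat-age structure, isoform complexity, correlated expression programs,
batch effects. Passing tests on this synthetic data demonstrates that the
statistics recover known planted structure under the stated noise models —
not that any particular biological dataset will show such structure.

**Problem sizes.** The shipped test and acceptance runs use 2,000-gene
backgrounds with 200-gene targets for null calibration (500 repetitions at
1,000 iterations), 500-gene genomes over 20 seeds for planted-enrichment
recovery (10,000 iterations, the default), 1 Mb / 100 motifs for the search
oracle, and 3 × 60 samples × 500 genes for the classifier. These sizes give
stable rates while keeping a full run in minutes on one CPU.

## Known limitations

* The planted-recovery criterion ("the planted stratum and nothing else, in
  ≥ 95% of 20 runs") sits close to the intrinsic false-positive rate of the
  significance rule: a null stratum passes `|Z| ≥ 2` plus FDR ≤ 5% with
  probability ≈ 4.5% when few strata are tested, so occasional runs with
  one spurious stratum are expected statistical behaviour, not a defect.
* The Monte Carlo null resamples genes uniformly; there is no GC-, length-
  or expression-matched resampling. Density normalisation by region length
  is the only compositional control, by design.
* SAM itself is not reimplemented; the permutation test above is a
  documented stand-in whose calls feed the same downstream analyses.
* Pyknon *discovery* is out of scope; motif lists are always inputs.
* Plotting is intentionally left to the caller: every curve and matrix is
  written as TSV.
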