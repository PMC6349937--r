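---
title: "Inferring peak-gene regulatory links from paired single-cell omics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring peak-gene regulatory links from paired single-cell omics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screglink)
```

## The problem

Joint profiling of chromatin accessibility (CA) and gene expression (GE) in
the same single cells makes it possible to ask which accessible
cis-regulatory elements (CREs) actually influence the transcription of which
genes, rather than inferring this indirectly from bulk correlations.
`screglink` takes a peak x cell fragment-count matrix, a gene x cell count
matrix, peak intervals and a TSS-aware gene annotation, and produces
peak-to-gene *regulatory links* by three complementary strategies, a binary
link x cell matrix recording the per-cell on/off state of every link, and
downstream summaries of that matrix (NMF signatures separating cell
identities, TF accessibility deviation scores, validation against chromatin
interaction data).

All genomic coordinates inside the package are BED-style 0-based half-open;
GTF input is shifted by one exactly once, on read. Matrices are oriented
features x cells throughout.

## Preprocessing

Peaks are kept when they show more than one fragment in at least 10% of
cells; genes when they are detected in at least 10% of cells
(`filter_features`; the boundary is inclusive, and a `strict` flag flips
it). Counts are normalized by pooled size-factor deconvolution
(`pooled_size_factors`): cells are ordered on a ring by library size, pools
of sizes 21, 26, 31, 36 and 41 are slid around the ring, each pool
contributes one linear equation (the summed factor of its members equals
the median ratio of the pooled profile to the average pseudo-cell), and the
stacked system is solved by least squares and rescaled to mean 1. Fewer
cells than the smallest pool fall back to library-size factors with a
warning; non-positive solutions are clipped. Pooling stabilizes the
per-cell ratios against the extreme sparsity of single-cell counts, which
is why it is preferred over plain library-size scaling.

## The three linking strategies

**Strategy 1 (accessibility only).** For each gene, peaks overlapping the
promoter (TSS ± 2 kb by default; the promoter half-width is a convention,
not a measured quantity, and is configurable) are correlated against every
*distal* peak within 1 Mb of the TSS. The correlation is a *weighted
Spearman* correlation: both vectors are ranked (average ranks on ties) and
a weighted Pearson correlation of the ranks is taken. The weights are the
exposure rows of an NMF of the accessibility matrix — one correlation per
signature — so that cell subpopulations do not cancel each other's signal.
A link is called when the maximum correlation over signatures and promoter
peaks exceeds 0.25 (one-sided: anti-correlation is never a link).

**Strategy 2 (accessibility x expression).** Identical machinery, but the
response is the gene's normalized expression vector and the weights come
from an NMF of the expression matrix. We weight by the subpopulation
structure of the response modality in each case; this pairing is a design
interpretation, and either H matrix can be supplied.

**Strategy 3 (per-cell active regions).** This is the only strategy that
yields a *per-cell* on/off state:

1. *TF activity.* Regulons (a TF plus its co-expressed targets) are built
   by a documented simplification of the SCENIC approach: candidate targets
   are genes with Spearman correlation ≥ 0.3 to the TF's own expression,
   optionally pruned to genes with a qualifying motif of that TF near
   their TSS; regulons smaller than 10 genes are dropped. Per cell, a
   regulon is scored by the area under its recovery curve over the top 5%
   of that cell's expression ranking (`recovery_auc`; the AUCell
   convention), normalized so that perfect packing of the regulon at the
   top scores 1. Each TF's AUC row is binarized by a two-component
   Gaussian mixture (EM, 10 seeded restarts, variance floor); the
   threshold is the smallest point between the component means where the
   posterior flips. When the components are indistinct (mean separation
   below half the summed standard deviations) the call falls back to
   mean + 2 sd, so unimodal rows come out all-inactive while a lone
   outlier is still flagged.
2. *Active regions.* Peak sequences are scanned with each TF's PWM on both
   strands (`scan_peak`). Scores are log2 odds against a uniform
   background. Because log-odds scores can be negative, "95% of the
   highest possible score" is made well-defined by shift-normalizing:
   a window is a hit when (score − min) / (max − min) ≥ 0.95, with the
   literal ratio available behind a flag. A peak is *active in a cell*
   when at least one TF has a hit in the peak and is called active in
   that cell — and, by default, the peak shows at least one fragment in
   that cell (`require_fragment`; the fragment requirement is our
   default because an unobserved peak carries no evidence of activity in
   that cell, and it is configurable).
3. *Link test.* For every gene and every peak within 1 Mb of its TSS, the
   gene's normalized expression is compared between cells where the peak
   is active and cells where it is not, by a Wilcoxon rank-sum test; a
   link is called at p < 0.05 (uncorrected by default, matching the
   screening character of the procedure; BH adjustment is available).
   Partitions leaving fewer than 3 cells on either side are recorded as
   untested. The link's per-cell state is the peak's active-mask row.

A complementary Pearson screen (`pairwise_correlation_screen`) reports
signed counts of significant peak-gene correlations at FDR < 10% over
TSS-window pairs, and `link_distance_distribution` summarizes the
peak-to-TSS distances of any link set.

### Wilcoxon p-values

The exact null distribution is used for tie-free splits up to a combined
n of 12; all larger or tied cases use the normal approximation with
mid-ranks, tie-corrected variance and continuity correction, plus an
Edgeworth fourth-moment term. The Mann-Whitney null is platykurtic at
small sample sizes (closed-form excess kurtosis
−(6/5)(m² + n² + mn + m + n) / (mn(N+1))), and the plain
continuity-corrected normal approximation misses the exact tail mass by
up to 0.037 at 3 + 3; the Edgeworth term brings the worst-case
disagreement over *all* tie-free splits with combined n ≤ 12 below 0.02
and vanishes as the samples grow, leaving large-sample behavior
untouched.

## NMF signatures and rank selection

`nmf_factorize` minimizes the Frobenius loss by multiplicative updates
from uniform-random initializations scaled to the matrix mean (seeds
derived from a master seed plus the restart index, so results are
bitwise reproducible). The best of 20 restarts supplies W and H; every
restart's W feeds the mean Amari distance, and per-restart connectivity
matrices (cells co-clustered when their H-column argmax agrees) are
averaged into a consensus matrix. Binary link matrices are factorized
as-is.

Rank selection over K = 2..6 scores each rank by three criteria: the
relative Frobenius *error drop* from the previous rank (the raw error is
monotone in K, so the drop — the elbow — is what carries information),
the mean Amari distance across restarts (restart stability), and the
cophenetic correlation of the consensus matrix (cluster stability,
computed by average-linkage clustering of 1 − consensus). Each criterion
ranks the candidates and the best mean rank wins. Ties are resolved
toward the rank with the larger error drop, then toward the smaller K:
on clearly block-structured matrices the two stability metrics saturate
(several ranks are all "perfectly stable" to within noise), and the
error elbow is then the only criterion that still discriminates.

The Amari distance between two factor matrices is computed from their
column cross-correlation matrix C as 1 − (Σ row maxima + Σ column
maxima)/(2K); it is exactly 0 when the columns match up to permutation
and positive rescaling, and it is symmetric. Signature-exclusive
features are rows of W whose normalized weight on one signature reaches
0.75, and cross-rank similarity regresses each higher-rank signature
onto the lower-rank W by non-negative least squares, normalized to
mixing proportions.

## TF accessibility deviations

A simplified chromVAR-style score: for motif m and cell c, the observed
aggregate fragment count over the motif's peaks is compared with the
count expected from the cell's depth and the motif peaks' pooled share
of all fragments, giving a raw deviation (obs − exp)/exp that is
identically zero when counts are exactly depth-proportional. Raw
deviations are z-scored against 50 background peak sets matched on mean
accessibility (quantile bins; optionally 2-D with GC content), removing
technical structure. A motif's variability is the standard deviation of
its z-score row; cell-state-specific motifs rank above matched null
motifs. Bias-corrected k-mer deviations and sampling-depth corrections
of the full chromVAR model are out of scope.

## Validation against chromatin interactions

A link is supported by a BEDPE interaction when one anchor overlaps the
link's peak and the other overlaps the gene's promoter (TSS ± 2 kb;
anchors may be widened by a slop). The promoter anchoring is a design
choice — interactions are anchored at promoters in the assays this
validates against — and either anchor assignment is accepted.
`validation_proportion` reports the supported fraction per strategy and
`strategy_overlap` the three-way Venn counts.

## The synthetic benchmark generator

`generate_paired_omics` plants three layers of ground truth in a
block-structured genome (blocks 3 Mb apart so 1 Mb search windows never
cross): *link blocks* holding one target gene and one motif-bearing peak
whose accessibility tracks the resident TF's cell-type activity while
the gene's expression shifts by the configured log2 effect when the
region is active; *decoy blocks* holding a motif-bearing peak next to
flat genes (honest null tests); and packed blocks holding TF genes,
their co-expression program targets, flat genes, and motif-free
promoter/background peaks. Accessibility is Poisson (baseline mean 2
fragments, x4 at type-active peaks); expression is negative binomial
(mean 5, size 2) with Bernoulli dropout.

Defaults describe the benchmark condition used by the tests and the
acceptance script: 300 cells in 3 equal types, 500 genes, 2000 peaks,
10 TFs each active in exactly one type, 100 planted links with a 1.0
log2 effect, seed 17 — desk-scale in well under a minute. Three
parameters are free choices the data do not pin down, set once to
realistic values: the TF/program on/off contrast is 4 log2 (lineage
markers are near-silent outside their lineage), each TF's gene and
targets share a per-cell log-normal activity factor with sd 0.8 (regulon
co-expression is co-fluctuation with shared TF activity, and without a
shared factor rank correlations between targets are capped near 0.15 by
count noise), and dropout is 0.15 (deep full-length single-cell RNA
libraries). Motifs are 12 bp consensus PFMs: at 8 bp a motif recurs by
chance ~30 times across 2000 x 500 bp of random sequence, which would
dissolve the planted block isolation; 12 bp keeps chance hits near zero
while staying within the JASPAR core length range.

What the generator does *not* emulate: realistic genome background and
GC structure, doublets, batch effects, continuous (non-discrete) cell
states, distance-dependent link strength, and trans-acting links.
Passing the benchmark therefore demonstrates that the machinery recovers
the planted generative structure at realistic noise — not that real
tissue will yield links at these rates.

## Numerical choices and degenerate inputs

- Constant vectors make correlations undefined: `weighted_spearman`
  returns NA with a warning, screens skip the pair.
- `nmf_factorize` drops all-zero rows/columns (with index bookkeeping),
  guards divisions with 1e-10, checks convergence every 10 iterations at
  relative tolerance 1e-6, and errors when K reaches the matrix
  dimensions.
- A constant consensus matrix has an undefined cophenetic correlation;
  1 is returned by convention with a warning.
- Ties in expression ranks are broken by stable gene order in
  `recovery_auc`, making the score deterministic.
- `sample_background_peaks` maps singleton bins to themselves with a
  warning; z-scores with zero background sd fall back to the raw
  deviation.
- The mark-class rules give bivalent precedence over inactive when both
  patterns are satisfied.

## Problem sizes

The test suite and the acceptance script run the full benchmark
condition (300 cells / 2000 peaks / 500 genes), one NMF rank scan over
K = 2..6 at 20 restarts, five permuted-mask null replicates (~800 null
tests), an exhaustive Wilcoxon comparison over all tie-free splits with
combined n ≤ 12, and 50 motif-scan oracle fixtures of 200 bp — chosen
as the smallest sizes at which every recovery property is stably
measurable.

## Known limitations

Strategies 1-2 test every (promoter, distal) pair independently and
inherit the usual caveats of correlation screens; no distance-decay
weighting or co-accessibility graphical model is applied. The regulon
builder is a correlation heuristic, not a gradient-boosted GRN; regulons
can be imported to bypass it. Motif scanning requires peak sequences
(or a precomputed hit table). The strategy-3 per-cell on/off state
equates "region active" with the motif/activity/fragment conjunction —
one of several defensible operationalizations, selectable via
`require_fragment`.
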