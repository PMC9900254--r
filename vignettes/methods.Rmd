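---
title: "Methods: co-accessibility, chromatin states and ISG regulation in ifnchrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-accessibility, chromatin states and ISG regulation in ifnchrom}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifnchrom)
```

# Scope and model

`ifnchrom` analyses how preexisting chromatin context shapes the cell
type–specific response to interferon-β. The object of study is the set of
STAT1/2 binding sites — loci where STAT1 and STAT2 ChIP-seq peaks overlap,
taken as a proxy for ISGF3 occupancy — and their relationship to
interferon-stimulated genes (ISGs) through promoter binding, distal
co-accessible links, and the chromatin state of the site. The package
implements the downstream statistics; upstream processing (alignment, peak
calling, differential expression) is out of scope and its results are
inputs.

All genomic coordinates are 0-based half-open (BED convention); the TSS is
the interval start on the plus strand and `end - 1` on the minus strand.
Two peaks are "the same locus" when they share at least 1 bp (configurable
via `min_overlap`); overlapping peaks from the two factors are merged to
their spanning interval so each union entry is one locus, and chains of
more than two overlapping peaks merge into one locus carrying all
contributing ids.

# Co-accessibility

For each STAT1/2 site, candidate partners are the 2-kb tiles lying fully
inside a 1-Mb window centred on the site. Tiles sit on a genome-anchored
grid so that nearby sites share tiles; the tile containing the site itself
is excluded. Accessibility is binarized (any fragment count ≥ 1 → open)
and the statistic is the per-cell Pearson correlation of the two binary
columns — the phi coefficient — computed across single cells with no
aggregation. Zero-variance columns yield missing correlations, which
propagate and are never called significant.

Cells enter the analysis through `select_balanced_cells()`: exactly 2,700
cells per (cell type, condition) group — the default mirrors the study
design this package models — chosen by matching each group's
fragment-count distribution to pooled quantiles with a deterministic
greedy sweep, so conditions are compared at matched depth.

The null model (`shuffle_null_threshold()`) permutes the accessibility
entries jointly over the full cells × peaks matrix: total density is
preserved and all structure (per-cell depth, per-peak rate, pair
correlation) is destroyed. Correlations are recomputed on the identical
site–tile pair layout, pooled over `n_shuffles` (default 10) shuffles, and
the significance threshold on *r* is the empirical 99th percentile of the
pooled null values. On a structure-free binary matrix with *n* cells the
null correlation is approximately normal with sd `1/sqrt(n - 1)`, so the
threshold is ≈ `qnorm(0.99)/sqrt(n - 1)` ≈ 0.045 at *n* = 2,700; matrices
with per-cell depth variation give a larger observed-to-null gap because
depth is real structure that the shuffle removes. A link is significant
iff *r* strictly exceeds the threshold (one-sided positive: negative
correlations are never "co-accessible") and the two-sided p-value from
`t = r√((n−2)/(1−r²))` with `n − 2` df is below α = 0.01. p-values are
deliberately not multiplicity-adjusted: the raw 0.01 level is part of the
procedure being modelled, and the expected false-call rate it implies is
what the calibration tests check. Comparing conditions, a pair is *gained*
if significant only in the treated condition, *lost* if only in the
reference, *stable* or *absent* otherwise — a flip of the significance
flag, with no additional magnitude test.

Each link also carries the percent-accessible QC covariate. The phrase
"average of cells that had site 1 or site 2 accessible" admits two
readings; the default is the mean of the two per-site accessible
fractions, and the alternative (fraction of cells with either member
open) is available via `mode = "either_open"`. On null data the link
correlation and this covariate are uncorrelated, which the tests verify.

# Expression thresholding

Baseline expression is transformed as `log10(TPM + 0.01)` — the
pseudocount keeps zeros finite and is configurable — and fit with a
two-component Gaussian mixture by EM with free weights, means and sds.
Initialization is a deterministic median split; the log-likelihood is
non-decreasing by construction and convergence is declared when its change
drops below `tol`. A collapsing component (sd under `sd_floor`) triggers a
jittered restart, with failure after `max_restarts`. Whether the original
analysis fit free or equal weights is not documented; free weights are the
more general choice and reduce to equal weights when the data support
them. The active/repressed threshold is the root of
`w_r N(x|μ_r,σ_r) = w_a N(x|μ_a,σ_a)` between the two means — a quadratic
in *x* (linear when the sds are equal), solved in closed form, with the
between-means root selected. Genes at or above the threshold are classified
active (closed lower bound, a stated convention).

# Regulation mechanisms

Each ISG receives three non-exclusive flags: a STAT1/2 site overlapping
its promoter window (TSS ± 1 kb); a gained link connecting a *distal*
STAT1/2 site (one not in this gene's promoter window) to the gene; a lost
link likewise. A link "connects to" a gene when its tile anchor overlaps
the promoter window or the gene body extended by a 5-kb proximal margin
(configurable) — gene bodies are included because distal regulation is
observed both directly at promoters and via gene-body contacts. The single
reported category resolves by the priority promoter > gained > lost >
other: promoter binding dominates regardless of additional distal links,
and gained precedes lost as an implementation choice recorded here because
genes carrying both are not distinguished by the modelled analysis. Flags
are retained so multi-mechanism genes can be counted. Distal partners are
typed `ISG-promoter` iff they overlap the promoter window of *any* ISG;
all other partners — including non-ISG promoters — are `enhancer`.
Induction differences between categories use two-sided Wilcoxon rank-sum
tests (normal approximation with tie correction; exact for groups under
10), with categories under 3 genes skipped and star bins at 0.05, 0.01,
0.001 and 0.0001.

# Chromatin states

Per-site feature values are enrichments over matched controls: counts in
±1-kb windows around site centers are scaled by library size and a
per-sample fragment-length scalar, one pseudo-read is added to both signal
and control before forming the rate ratio (so equal signal and control
give exactly 1 and zero controls stay finite), and replicates are
averaged. Enrichments are z-scored per feature before clustering —
otherwise high-dynamic-range marks dominate the distance — with a raw
mode available. `stats::kmeans` with `n_init` restarts keeps the best
inertia; k defaults to 5, the biologically motivated state count, and the
mean silhouette over k = 2…20 is always reported as the check on that
choice.

Centroid naming is rule-based on standardized values: Bivalent requires
both H3K4me3 and H3K27me3 elevated; Active Promoter H3K4me3 with
H3K9ac/H3K27ac; Active Enhancer H3K4me1 with H3K27ac; Poised H3K4me1
without other marks; Repressed H3K9me3 or H3K27me3 without active marks.
Each rule yields a score per centroid and the one-to-one naming maximizes
the total score over all 5! permutations, which makes the assignment
invariant to cluster index order and resolves near-ties (a bivalent
centroid also scores on the repressed rule, but the permutation optimum
separates them); exact ties abort with a centroid dump rather than guess.

State transitions between cell types are plain contingency tables over a
shared site universe, so marginals equal the per-cell-type state
histograms exactly. Feature–binding correlations use the mean of STAT1 and
STAT2 signal at 1 h as the binding signal and Pearson correlation on
`log2(value + 0.01)` — the log stabilizes the right-skewed enrichment
scale; the axes of the modelled analysis are not documented, so this
choice is recorded here. Correlations are emitted both pooled over the
combined cell-type-specific sites and per cell type, since the modelled
figure is ambiguous between the two.

# Synthetic data: what it emulates and what it does not

The generators reproduce the *statistical structure* the analysis relies
on, not the biology of any genome:

- `generate_accessibility_matrix()` draws per-cell fragment counts
  log-normal (`sdlog = 0.5` by default, a typical depth spread for
  single-cell ATAC; `sdlog = 0` gives the structure-free matrices used for
  calibration) and scales each cell's open probability by its relative
  depth. A planted link adds a per-cell latent Bernoulli "activity" with
  probability `effect × baseline_rate`, OR-ed into both members — the
  simplest generative mechanism whose phi correlation rises monotonically
  with effect strength (≈ 0.45 at effect 0.9 and baseline 0.1). Baseline
  accessibility defaults to 0.1 per 2-kb tile; per-peak rates of the real
  data are not published, so this is a configurable package choice, not a
  calibration.
- `generate_expression_table()` draws baseline log₁₀ expression from the
  active/repressed mixture and multiplies ISGs by a (possibly per-gene)
  induction fold at treated conditions, plus log-normal measurement noise.
- `generate_binding_landscape()` places peaks in disjoint slots with an
  exact number of reciprocal STAT1–STAT2 overlaps and puts a configurable
  fraction of overlap loci within ±1 kb of a TSS.
- `generate_feature_matrix()` adds isotropic Gaussian noise to the five
  archetype profiles in `chromatin_archetypes()`.

Not emulated: read-level data, sequence content, doublets, batch effects,
distance decay of co-accessibility, and correlated (non-isotropic) feature
noise. Passing tests therefore demonstrate the correctness and calibration
of the statistics under the assumed generating model, not robustness to
every artifact of real single-cell data.

# Numerical choices and problem sizes

- All generator and pipeline randomness flows through one seeded stream
  per call (`with_seed`), restoring the caller's RNG state; the pipeline
  derives per-stage seeds from one master seed, so stages can be rerun in
  isolation and manifests are checksum-stable.
- The silhouette scan caps k at the number of distinct profiles; constant
  features are centered but not scaled.
- The separation/noise ratio of the clustering suites is defined as the
  minimum pairwise archetype distance divided by the RMS noise
  displacement of a site (`noise_sd × √p` for p features) — the
  cluster-scale noise magnitude — so ratio 3 means centers three times as
  far apart as a typical point's displacement.
- Equidistant nearest-TSS ties resolve to the lexicographically smaller
  gene id. Nearest-gene assignment is deliberately the simple
  center-to-TSS distance; regulatory-domain association rules of tools
  like GREAT are not reproduced, and the docs flag this.
- Test and demo problem sizes are chosen desk-scale: 2,700-cell matrices
  with tens of columns for calibration and recovery suites (20 seeds),
  n = 10,000 for mixture recovery, 250 sites for clustering suites, and a
  demo pipeline with ~10⁴ candidate pairs. These sizes give Monte-Carlo
  error comfortably inside the asserted tolerances.

# Known limitations

The shuffled null preserves only total density; per-cell depth variation
is real structure, so on depth-heterogeneous matrices the fraction of
pairs above the null threshold exceeds the nominal 1% even without planted
links — as in the modelled procedure itself. The t approximation for
correlation p-values is asymptotic and anti-conservative for very sparse
columns; the percent-accessible covariate exists precisely to let users
filter such links. The regulation classifier attributes links to genes by
fixed windows and does not model secondary targets (ISGs induced by
downstream transcription factors), which remain "other".
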