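# ifnchrom

Chromatin-context analysis of the cell type–specific interferon-β (IFNβ)
response, packaged as a tested, reusable R pipeline.

Type I interferon stimulation activates interferon-stimulated genes (ISGs)
through the ISGF3 complex (STAT1–STAT2–IRF9) binding interferon-stimulated
response elements (ISREs). Which ISREs are actually bound — and therefore
which ISGs respond — differs between cell types, and the difference is
largely set by the preexisting chromatin context. `ifnchrom` implements the
downstream analyses needed to dissect this:

- **Binding-site classification** — STAT1 and STAT2 ChIP-seq peak lists are
  intersected into `STAT1`-only, `STAT2`-only and `STAT1/2` sites (the
  ISGF3 proxy: loci where both factors overlap, merged to their spanning
  interval), compared across cell types, and annotated against promoters
  (TSS ± 1 kb).
- **Single-cell co-accessibility** — for each STAT1/2 site, per-cell
  Pearson correlations (the phi coefficient on binary data) between the
  site and every 2-kb tile in a 1-Mb window, computed over 2,700
  depth-balanced cells per condition without any cell aggregation. The
  significance threshold on *r* is the empirical 99th percentile of a null
  built by jointly shuffling the accessibility matrix over cells and peaks;
  a link is called when *r* exceeds that threshold **and** its two-sided
  p-value (t approximation, *t = r√((n−2)/(1−r²))*) is below 0.01. Links
  present only after treatment are *gained*; links present only before are
  *lost*.
- **Expression thresholding** — baseline log₁₀ expression is fit with a
  two-Gaussian (active/repressed) mixture by EM; the component-density
  intersection between the two means is the active/repressed threshold.
- **Regulation mechanisms** — each ISG is flagged for promoter-bound
  STAT1/2, gained distal links and lost distal links, and resolved to one
  category by the priority promoter > gained > lost > other; distal
  partners are typed ISG-promoter vs enhancer; categories are compared on
  induction with Wilcoxon rank-sum tests.
- **Chromatin states** — per-site enrichments of six histone marks
  (H3K4me1, H3K4me3, H3K9ac, H3K27ac, H3K9me3, H3K27me3) and ATAC are
  z-scored and k-means clustered (k = 5, with a 2–20 silhouette scan);
  centroids are named Active Promoter / Active Enhancer / Bivalent /
  Poised / Repressed by mark-combination rules; state transitions between
  cell types are tabulated and untreated features are correlated with
  subsequent STAT1/2 binding (mean of STAT1 and STAT2 signal at 1 h).
- **Synthetic data** — seeded generators emulate the full study structure
  (binary accessibility with planted latent-factor links, bimodal
  expression with per-ISG induction folds, peak sets with controlled
  overlaps, 5-archetype feature profiles), so every stage is testable with
  known ground truth and no downloads.

## Worked example

The `analysis/` directory holds the numbered workflow; each script is a
thin driver over the package and writes its tables under
`results/analysis/`:

```sh
Rscript analysis/01_simulate.R        # synthetic study inputs
Rscript analysis/02_sites.R           # site classification + ISG set arithmetic
Rscript analysis/03_coaccessibility.R # links, shuffled null, gained/lost
Rscript analysis/04_mechanisms.R      # thresholds + regulation mechanisms
Rscript analysis/05_states.R          # chromatin states + binding correlations
```

Stage 3 prints, for the simulated matrix (2,700 balanced cells per
condition, baseline accessibility 0.1, nine planted links at ISG loci):

```
[0h] null 99th-percentile r threshold: 0.0472
[0h] significant links: 309 of 12322 pairs (2.51%)
[6h] null 99th-percentile r threshold: 0.0469
[6h] significant links: 318 of 12322 pairs (2.58%)
link deltas: 305 gained, 296 lost, 13 stable
planted links recovered with the correct status: 9 of 9
```

The null threshold sits at the analytic value for 2,700 cells
(≈ 2.326/√2699 ≈ 0.045, here slightly higher because per-cell depth varies)
and every planted link is recovered with the correct gained/lost status.
Stage 4 then resolves the mechanism categories and their induction
ordering:

```
mechanism categories:
  gained     lost promoter
       6        3       12
  category_a category_b n_a n_b median_a median_b           p stars
1   promoter     gained  12   6 3.343207 2.869571 0.041478130     *
2   promoter       lost  12   3 3.343207 1.223158 0.008791209    **
3     gained       lost   6   3 2.869571 1.223158 0.023809524     *
```

— the planted ordering (promoter-bound ISGs induced most, lost-link ISGs
least) is recovered from the expression table. Stage 5 reports a silhouette
optimum at k = 5, perfect recovery of the generating states (ARI 1.0) and
the expected sign pattern of feature–binding correlations (positive for
ATAC/H3K27ac, negative for H3K27me3).

A one-call version of the same workflow is available in R:

```r
library(ifnchrom)
res <- run_pipeline(default_config(seed = 1))
```

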