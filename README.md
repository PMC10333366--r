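# chorkinetics

Post-replication histone-mark restoration kinetics from ChOR-seq time
courses.

ChOR-seq (Chromatin Occupancy after Replication) pulse-labels newly
replicated DNA with EdU, immunoprecipitates a histone mark (here,
H3K27me3), captures the EdU-labeled fragments, and sequences them at a
series of timepoints after replication. The analytical question is *how
fast* a mark returns to its pre-replication level at each genomic locus,
and what distinguishes fast- from slow-restoring chromatin. This package
implements the complete downstream analysis as a tested R pipeline for
epigenomics analysts:

- **Replicated-region calling** — raw EdU counts are tested in 1-kb
  windows every 100 bp against a global Poisson background; windows with
  Benjamini–Hochberg-adjusted p < 1e-4 are merged into replicated
  regions, and peak "EdU coverage" is the fraction of mark peaks
  overlapping them.
- **Spike-in normalization** — reference-adjusted RPKM: each sample is
  scaled by 10^6 / (spike-in genome reads) and each region by
  1000 / length, so signal is comparable across timepoints (ChIP-Rx
  convention with exogenous *Drosophila* chromatin).
- **Restoration rate (RR)** — the core statistic. For each peak the
  normalized time course y(t) at t = 0, 2, 4, 6 h is fitted with a
  quadratic f(t) = a·t² + b·t + c (ordinary least squares). With
  T_max = argmax f on [T0, Tx], the restoration rate is the average
  derivative over n = 10000 equally spaced points spanning [T0, T_max]:

      RR = (1/n) · Σᵢ f′(tᵢ),  f′(t) = 2a·t + b

  Because f′ is linear this equals f′ at the grid midpoint and converges
  to the mean slope (f(T_max) − f(T0)) / (T_max − T0). Peaks are grouped
  into quartile clusters (super-fast / fast / slow / bottom-slow) by
  descending RR, and a spatial profile of RR over five 300-bp windows
  spanning ±750 bp around each peak summit localizes where restoration
  is fastest.
- **Restoration-pattern clustering** — per-peak trajectories are
  z-scored and clustered with seeded fuzzy c-means (k = 3,
  fuzzifier 2); clusters are named early / intermediate / late by their
  centroid's argmax time.
- **Group statistics** — strand-aware promoter-target assignment
  (TSS ± 2 kb), paired two-sided Wilcoxon signed-rank tests (exact by
  convolution up to n = 25, tie-corrected normal approximation beyond),
  quartiles of between-condition signal change, and a summary of
  mis-expressed mark-target genes.
- **Synthetic data generator** — ChOR-seq-like inputs with known kinetic
  ground truth (quadratic trajectories with class-structured argmax
  times, Poisson counts, per-timepoint spike depths, a 70 % EdU-labeled
  peak subset), so every stage is testable without sequencing data.

## Worked example

The analysis is organised as numbered drivers under `analysis/`
(simulate → call regions → normalize → restoration rate → pattern
clustering → group comparisons), each writing its tables under
`results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

which prints, among other lines:

```
EdU coverage: 70.0% of 1000 peaks
Spearman(true RR, estimated RR) = 0.968
summit profile (mean RR at -600/-300/0/+300/+600 bp): 8.68 11.60 14.19 11.29 8.65
cluster proportions: early 29.57%, intermediate 29.43%, late 41.00%
adjusted Rand index vs truth: 0.959
median RR: reference 14.61, perturbed 7.59 (52% remaining)
misregulated targets: 299 total, 43.81% up, 56.19% down
```

Reading these: 70 % of simulated peaks fall in called replicated regions
(the generator's labeled fraction); estimated restoration rates track
the true mean slopes (Spearman 0.97); RR is maximal at the peak summit
and decays outward; trajectory clustering recovers the configured
early/intermediate/late classes (ARI 0.96, proportions within 2
percentage points of 28.73/30.87/40.30 %); the perturbed condition
(curvature halved, emulating impaired restoration) retains ~50 % of the
reference median rate at overwhelming signed-rank significance; and
43.81 % of the 299 significantly mis-expressed mark-target genes are
upregulated.

The same computations are available programmatically:

```r
library(chorkinetics)
res <- run_chor_pipeline(chor_config(seed = 1L), outdir = "results/run")
res$coverage$fraction      # EdU coverage
head(res$rr)               # per-peak a, b, c, RSS, Tmax, RR, quartile
res$cluster_props          # early/intermediate/late proportions
```

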