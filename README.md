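# ginifano

Cluster-aware weighted ensemble clustering for single-cell RNA-seq:
detect **common and rare cell types in the same analysis**.

Methods tuned for common populations (highly variable genes + k-means)
cannot resolve clusters of a handful of cells; methods tuned for rare
populations (genes expressed in few cells + density clustering) merge
the major populations. `ginifano` runs both and combines them with
cluster-aware weights:

1. **Rare-cell stage** — genes are scored by the Gini index (twice the
   area between the Lorenz curve of a gene's expression and the
   diagonal), LOESS-normalized against maximum expression; cells are
   clustered by DBSCAN on the Jaccard distance over binarized high-Gini
   genes.
2. **Common-cell stage** — top Fano-factor (variance/mean) genes, 50
   principal components, k-means with kmeans++ restarts; k chosen by the
   gap statistic.
3. **Weighted consensus** — each partition becomes a connectivity matrix
   M, combined as M̄ᵢⱼ = wᵢⱼᴳ Mᵢⱼ(Pᴳ) + wᵢⱼᶠ Mᵢⱼ(Pᶠ) with wᵢⱼᴳ + wᵢⱼᶠ = 1.
   A cell's rare-stage weight is a logistic function of its cluster-size
   proportion x, w̃ᴳ(x) = 1 − 1/(1 + e^{−(x−μ′)/s′}), so small clusters
   trust the rare-cell method and large clusters the common-cell method;
   a pair takes the max of its two cell weights. The final partition
   minimizes ‖M̄ − U‖² over k-block connectivity matrices via k-means on
   the rows of M̄.

The package also ships a negative-binomial count simulator with planted
common and rare clusters, agreement metrics (per-type MCC, NMI, ARI,
confusion maps), and a composite tSNE view (two Fano dimensions + one
Gini dimension). See the methods vignette
(`vignettes/ensemble-clustering.Rmd`) for the model details and design
choices.

## Worked example

Simulate a scaled-down benchmark — two common clusters (300 and 150
cells) and four rare ones (8/5/4/3 cells) — and run the pipeline:

```r
library(ginifano)

sim <- simulate_counts(cluster_sizes = c(300, 150, 8, 5, 4, 3),
                       n_genes = 6000, n_low_sig = 20, n_high_sig = 20,
                       seed = 7)
fit <- run_ensemble(sim$counts, min_genes_per_cell = 200, k_fano = 2,
                    ref_labels = sim$labels, seed = 11)
fit
#> Weighted ensemble clustering
#>   1238 genes x 470 cells after filtering (from 6000 x 470)
#>   rare-cell stage:   5 clusters (DBSCAN, 36 high-Gini genes, 0 noise cells)
#>   common-cell stage: 2 clusters (k-means on 50 PCs)
#>   consensus:         6 clusters (mu = 0.05, s = 0.0125, f = 0.025)
#>   consensus cluster sizes: 300, 150, 8, 4, 3, 5
#>   vs reference: ARI = 1.000, NMI = 1.000
```

Reading the output: the rare-cell stage found the four planted rare
clusters but merged the two common ones into a single large cluster (5
clusters total); the common-cell stage separated the two common clusters
but absorbed every rare cell; the weighted consensus recovered all six
planted clusters exactly (adjusted Rand index 1 against the truth).
`tidy(fit)` returns the per-cell assignments of all three partitions,
`glance(fit)` a one-row summary, and `autoplot(fit)` the composite tSNE
(after running with `compute_tsne = TRUE`).

Per-type detection scores and the confusion map live in `fit$metrics`:

```r
fit$metrics$mcc_per_type   # one-vs-rest MCC per planted cluster (all 1 here)
fit$metrics$confusion      # proportion of each true cluster per consensus cluster
```

A thin command-line front end with `simulate` / `run` / `evaluate` /
`viz` subcommands is installed at `inst/cli/ginifano`.

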