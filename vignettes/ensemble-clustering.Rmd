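---
title: "Cluster-aware weighted ensemble clustering: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cluster-aware weighted ensemble clustering: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ginifano)
```

## The problem

Clustering methods tuned for common cell populations select features
(highly variable genes) that wash out rare populations, while methods
tuned for rare populations select features (genes expressed in a handful
of cells) that cannot resolve the major structure. Averaging the two
results does not help: an unweighted consensus treats every disagreement
as a compromise to be split. `ginifano` instead runs both kinds of
clustering and combines them with *cluster-aware* weights, so each method
is trusted exactly where it is strong — the rare-cell method on small
clusters, the common-cell method on large ones.

## The two base stages

**Rare-cell (Gini) stage.** For each gene the Gini index is twice the
area between the Lorenz curve of its expression across cells and the
diagonal; equivalently

$$G = \frac{\sum_i \sum_j |x_i - x_j|}{2 n^2 \bar x},$$

computed here in the $O(n \log n)$ sorted form. $G$ is near 1 for a gene
expressed in very few cells — the signature of a rare-population marker —
but it also trends with expression level, so raw values are normalized by
a two-step LOESS of `gini_raw` on `log2(max_expr + 0.1)`: a first fit
over all genes, then a refit excluding genes whose first-pass residual
exceeds the 90th percentile, so genuinely high-Gini genes do not drag the
trend toward themselves. The residual from the second fit is the
normalized Gini; genes with a one-sided normal-tail p-value below 1e-4
(location and scale estimated from all residuals; a median/MAD option
exists for heavy contamination) are the high-Gini features. Cells are
binarized over those features (count > 0) and clustered by DBSCAN on the
Jaccard distance $d(i,j) = 1 - |A_i \cap A_j|/|A_i \cup A_j|$. Cells in
low-density regions are labeled noise (cluster 0).

**Common-cell (Fano) stage.** The Fano factor (sample variance over
mean) flags genes that vary across the major populations. The top 1000
genes by Fano factor are reduced to 50 principal components (per-gene
centering, no other transform — raw UMI counts carry the signal the
stage needs; a `log1p` option exists but is off by default), and cells
are clustered by k-means. The number of clusters defaults to the gap
statistic: dispersion compared against reference data drawn uniformly
over the PCA-aligned bounding box, with the first-SE-max rule.

## The weighted consensus

Each stage yields a partition, encoded as a connectivity matrix
($M_{ij} = 1$ when cells $i,j$ share a cluster). The consensus
association is the entrywise convex combination

$$\bar M_{ij} = w^G_{ij} M_{ij}(P^G) + w^F_{ij} M_{ij}(P^F), \qquad
w^G_{ij} + w^F_{ij} = 1 .$$

Weights are cluster-aware. Each cell carries a rare-stage weight that is
a logistic function of the proportion $x_i$ of cells in its Gini
cluster,

$$\tilde w^G_i = 1 - \frac{1}{1 + e^{-(x_i - \mu')/s'}},$$

and a constant common-stage weight $\tilde w^F_i = f'$. A pair takes the
*maximum* of its two cell weights (a pair is judged by its rarer member)
and the weights are then normalized to sum to one. Users specify the
interpretable triple $(\mu, s, f)$: $\mu$ is the cluster proportion at
which the two stages are trusted equally, $s$ the width of the
hand-over, and $f$ the overall pull of the common-cell partition. These
map to the internal parameters by $f' = f/(1-f)$, $s' = s$, and
$\mu' = \mu + s'\,\mathrm{logit}(f')$, inverting
$f' = 1 - 1/(1+e^{-(\mu-\mu')/s'})$. Because that relation confines $f'$
to $(0,1)$, $f$ must stay below 0.5; `derive_params()` enforces this and
round-trips with `recover_params()` to machine precision.

```{r}
derive_params(mu = 0.05, s = 0.0125, f = 0.025)
```

Defaults: $\mu = 0.05$ (clusters under 5% of cells are "rare"),
$s = 0.0125$, $f = 0.025$. $\mu$ and $s$ encode the working range of the
rare-cell stage — DBSCAN with `min_pts = 3` cannot certify clusters
smaller than three cells, and clusters above a few percent are the
common stage's territory. The choice of $f$ is governed by a scaling
argument: in the row-space k-means that extracts the final partition, a
rare cell contributes a handful of strong within-cluster associations
but $n$ weak cross-associations of size $w^F$, so its common-stage
membership — which for a rare cell is sampling noise, not signal — can
overrule its rare-stage assignment unless
$w^F \lesssim \sqrt{n_{\min}/n}$ with $n_{\min}$ the smallest cluster of
interest. For thousands of cells that bound is a few percent; $f = 0.025$
sits comfortably inside it, and the benchmark simulation confirms that
larger values let a single stray Fano assignment split a planted
six-cell cluster. All three parameters remain exposed.

**Noise cells.** DBSCAN noise cells get $\tilde w^G_i = 0$: the rare
stage offers no confident assignment for them, so their pairs fall back
to the common-cell partition. Their cluster proportion is reported as
`NA`; the proportion denominator for real clusters includes noise cells.

**Extracting the final partition.** $\bar M$ is a probabilistic
co-clustering; a hard partition is obtained by minimizing
$\lVert \bar M - U \rVert^2$ over connectivity matrices $U$ with
`k_final` blocks. With an orthogonality constraint this becomes k-means
on the rows of $\bar M$, which is what `final_cluster()` runs. The
relaxation is exact in the operating regime — consensus matrices whose
two ingredient partitions are coherent (the coarse one merges blocks of
the fine one); for incoherent random associations the k-means optimum
can differ from the exhaustive minimizer, which the test suite
demonstrates by enumeration. `k_final` defaults to the number of common
clusters plus the number of Gini clusters below the $\mu$ threshold
(`choose_k_final()`); the rule is logged and can be overridden.

## k-means and the gap statistic

All k-means calls use kmeans++ seeding followed by Lloyd iterations
(at most 300), with 20 restarts and the best objective kept. Restarts
draw from one sequential RNG stream, so results are reproducible from a
single seed and the best objective is non-increasing in the number of
restarts. kmeans++ matters here: consensus rows contain tiny, far-away
blocks (the rare clusters), which uniform random seeding essentially
never hits; distance-weighted seeding finds them reliably. The gap
statistic uses B = 20 uniform reference sets by default and the
`firstSEmax` rule. Its dispersion uses unsquared distances (the
convention of the canonical `clusGap` implementation): in embeddings
with a few far outliers — exactly what rare cells are in the Fano space —
the squared-distance variant rewards splitting the outliers off as a
spurious extra cluster, while the unsquared form keeps the statistic on
the bulk structure. The squared variant remains available
(`d_power = 2`).

## The simulator

`simulate_counts()` generates the benchmark regime used throughout the
package: negative-binomial UMI counts (variance $m + \alpha m^2$,
$\alpha = 0.1$) for 23,538 genes over planted clusters of
2000/1000/10/6/4/3 cells. Cluster signatures are made by permuting gene
labels: per cluster, 100 lowly expressed (mean < 10) and 100 highly
expressed (mean > 10) genes are drawn disjointly from all other
clusters' signatures, and the count rows of the combined set are
shuffled within the cluster's cells (a shuffle moving fewer than half
the genes is re-drawn). A low gene that inherits a high gene's counts
becomes a marker: strong inside the cluster, near-silent elsewhere.

Baseline gene means follow a zero-inflated log-normal: 80% of genes are
silent (mean $10^{-5}$) and the rest draw from
$\mathrm{lognormal}(1.6, 0.8)$. This mirrors two facts about real UMI
matrices that a single log-normal cannot reproduce at once: most
annotated genes are never detected (the standard ≥ 3-cells filter
removes the large majority of genes, here ~80% as in real data), while
several hundred genes still exceed the mean-10 cutoff needed for the
high stratum. The silent majority also gives the rare-cell stage its
working condition — high-Gini markers with near-zero baseline detection,
so that common cells have essentially empty binary profiles and collapse
into one DBSCAN cluster, as observed in real analyses.

One stochastic feature of the benchmark deserves note: rare cells carry
no common-cluster signature, so which common cluster the Fano stage
assigns them to is decided by sampling noise on genes orthogonal to the
common split. They are always absorbed into common-dominated clusters —
the stage cannot resolve them, which is its defining limitation — but a
borderline rare cell occasionally lands on the minority side. The
consensus weighting is designed so this does not matter.

What the simulator does *not* emulate: library-size variation between
cells, gene-gene correlation beyond the planted signatures, batch or
dropout structure beyond NB sampling, and continuous (trajectory-like)
heterogeneity. Passing the benchmark therefore shows the pipeline's
logic is correct under its own assumptions, not that it is robust to
every artifact of real data.

## Numerical choices

- LOESS uses interpolation with a fine cell size (0.05) so the fitted
  surface reproduces the local regressions to machine precision;
  prediction sites are clamped to the refit's covariate range so genes
  excluded as outliers still receive a trend value rather than `NA`.
- Jaccard distance between two cells with empty profiles is 0 (they are
  indistinguishable), and the DBSCAN neighborhood count includes the
  point itself, so `min_pts = 3` certifies a three-cell cluster.
- DBSCAN expands clusters in cell order from the first-seen core point,
  making labels deterministic for a fixed ordering; the test suite pins
  agreement with an independent reference implementation.
- PCA fixes each component's sign by making its largest-magnitude gene
  loading positive.
- Top-Fano selection breaks ties lexicographically by gene id.
- The consensus matrix is assembled in row blocks (`block_size`), so
  peak memory beyond the output is O(block × n).
- Filters apply exactly one gene pass then one cell pass, in that order;
  re-application after cell removal may drop further genes and is left
  to the caller.

## Problem sizes used by the tests

Unit tests run a scaled-down benchmark (2 common + 4 rare clusters,
300/150/8/5/4/3 cells, 6,000 genes, 20 + 20 signature genes) which
preserves the full-size regime; the acceptance suite runs the full
2000/1000/10/6/4/3 × 23,538 configuration once and shares the fit across
checks, with 20 gap-statistic replicates at B = 10 reference sets each.

## Limitations

- The ensemble combines exactly two base partitions; extending to more
  is straightforward algebra but out of scope.
- Output is a hard partition; the soft information in $\bar M$ is
  available to the user but no probabilistic assignment is returned.
- The consensus matrix is dense (n × n); very large data sets need the
  block size tuned and, eventually, a sparser representation.
- The gap statistic is a starting point for choosing k, not an oracle;
  inspect the Fano-stage map and marker expression before trusting a
  borderline k.
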