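---
title: "Methods: genotype-contrasted analysis of the monocyte-to-macrophage waterfall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-contrasted analysis of the monocyte-to-macrophage waterfall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

Blood Ly6C-high monocytes enter the colonic lamina propria and differentiate
through intermediate states into mature MHCII+ macrophages — the "monocyte
waterfall". `scwaterfall` implements a complete droplet scRNA-seq analysis of
this continuum contrasted between two genotypes (vehicle-treated control vs a
tamoxifen-induced conditional knockout, "cKO"): per-sample UMI matrices are
merged without down-sampling, cells and genes are quality-filtered with fixed
thresholds, expression is normalized with pool-based deconvolution size
factors, variance is decomposed into technical and biological components for
a denoised PCA, cells are clustered by Ward linkage with a dynamic tree cut
and annotated against reference expression profiles by a Fisher-exact
overlap test, the differentiation topology is summarized by a
self-organizing map with its minimal spanning tree, condition shifts are
mapped as differential 2D kernel densities, and per-cluster pseudo-bulk
profiles are tested for differential expression with a negative-binomial GLM
followed by a competitive gene-set test. A synthetic-data generator with
known ground truth makes every stage testable without external data.

```{r pipeline}
library(scwaterfall)
design <- simulation_design(seed = 1)
sim <- simulate_waterfall(design)
run <- run_pipeline(sim,
                    reference = simulate_reference(design),
                    gene_sets = list(APOPTOSIS = default_apoptosis_genes()))
```

## Quality control

Thresholds are fixed values derived from bimodal distributions of per-cell
summaries, collected in `analysis_config()`:

* a cell is kept iff `log10(libsize) >= 2.8` (smallest admissible integer
  library size: 631 UMIs), `log10(n_features) >= 2.6` (smallest admissible
  feature count: 399 genes), its mitochondrial UMI fraction is at most 5%
  (exactly 5% is kept, exclusion is strictly ">5%"), and it carries no
  hemoglobin UMIs at all;
* a gene is kept iff the log2 of its mean CPM over QC-passing cells is at
  least 0.005, computed after cell QC (the order matters: gene abundance is
  defined on the retained cells).

Mitochondrial genes are recognized by the case-insensitive `mt-` symbol
prefix and hemoglobin genes by the `Hba*`/`Hbb*` prefixes; both lists are
configurable because prefix matching is a convention, not a gene-list
ground truth.

## Normalization and variance decomposition

Size factors come from the pooled deconvolution estimator (scran): summing
cells into overlapping pools avoids the dominance of zeros, and per-cell
factors are recovered by least squares and rescaled to unit mean. The pool
sizes default to 21–101 in steps of 20, capped at the number of available
cells; pre-clustering before pooling is available but off by default.
Log-expression is `log2(count / factor + 1)`.

The mean–variance trend is a degree-1 loess of the per-gene variance on the
per-gene mean of log-expression with span 0.05 (a small span fits the sparse
high-expression tail); queries outside the fitted range clamp to the nearest
fitted point and fitted variances clamp at zero. The trend value at a gene's
mean is its technical component; the residual (possibly negative) is the
biological component, and the decomposition conserves the total variance
exactly. PCA retains the smallest number of leading components whose
discarded complement carries no more variance than the summed technical
component, with a floor of two components. PCA is run twice: on the top-500
most-variable-gene matrix (embedding, clustering, density maps) and on the
full filtered matrix (the denoised scores feeding the SOM); whether the
published analysis restricted PCA to variable genes is ambiguous, so both
surfaces are exposed. Components are centered but not scaled to unit
variance, and scores are sign-canonicalized (the largest-magnitude score of
each component is positive) so truncated and exact SVD agree and reruns are
byte-identical. t-SNE (perplexity 30) is delegated to a Barnes–Hut
implementation and seeded.

## Clustering, markers, annotation

Cells are clustered by Ward's criterion on Euclidean distances between
normalized log-expression profiles (the HVG-restricted matrix by default;
distances computed via the Gram matrix for speed, identically to
`stats::dist`). The dynamic tree cut is a simplified height-gap algorithm:
starting at the root, a branch splits into its children when the gap at its
top (branch height minus tallest child height) exceeds `gap_factor` times
the standard deviation of the merge heights inside the branch; clusters
smaller than `min_cluster_size` (default 20) are dissolved and their cells
assigned to the nearest retained centroid. `gap_factor = 3` was calibrated
on generic Gaussian configurations — a single blob must stay whole while
20-sigma-separated blobs must split — and is exposed for tuning; adaptive
per-branch cutting is what lets clusters sit at different heights of the
dendrogram.

Markers come from unmoderated Welch comparisons of log-expression for every
ordered cluster pair; within a focal cluster genes are ranked by p-value
among positive log-fold-changes, and the cluster's top-set is the union of
the top 10 genes per comparison. An empirical-Bayes moderated fit would
shrink variances across genes; the unmoderated Welch statistic is a
recorded simplification.

Annotation follows the pseudo-bulk enrichment route: control cells of each
cluster are summed into one profile; pooled nonzero log2(CPM+1) values of
all profiles are fitted with a two-component Gaussian mixture (mclust, with
a deterministic order-statistic initialization subset) and genes are called
expressed above the equal-posterior point — when the BIC prefers one
component the pooled median is used instead, with a warning. Each cluster's
expressed set is tested against every reference's expressed set with a
one-sided Fisher exact test (the hypergeometric upper tail; "significance
of the overlap" is an enrichment question, so the test is one-sided) over
the shared gene universe of all filtered genes, BH-adjusted across
references within each cluster; up to ten significant references are
reported sorted by decreasing odds ratio, infinite odds ratios first.

## Topology and density maps

The SOM is a batch map on a 9×9 grid over the first 30 denoised principal
components. The neighborhood is Gaussian with width `radius/4`, the radius
shrinking linearly from half the larger grid dimension to 1; the final
fifth of the epochs (at least two) are winner-only updates with empty-node
repair (an unoccupied node is relocated onto the worst-quantized cell), so
the codebook converges onto the data and training is deterministic given
the seed. The minimal spanning tree over the codebook uses Kruskal's
algorithm with index tie-breaking. Per-node condition enrichment is the
normalized cKO share `(n_cko/N_cko) / (n_cko/N_cko + n_ctrl/N_ctrl)`;
normalizing by the condition totals prevents unequal condition sizes from
biasing every node toward the larger group.

2D densities use a product-Gaussian KDE with the normal-reference bandwidth
`1.06 * min(sd, IQR/1.34) * n^(-1/5)` per axis on a 100×100 grid spanning
the data range ±5%; the rule is pinned explicitly because KDE scaling
conventions differ between libraries. Condition densities are computed on
the shared (union-range) grid and the differential map is
`log2(d_cko + 1e-3) - log2(d_ctrl + 1e-3)`; writing the ratio as a
difference of logarithms makes condition swap bitwise antisymmetric. The
prior of 1e-3 regularizes empty regions. Mass smoothed past the grid
margins is not re-normalized; at the sample sizes used here the integral
deficit is well below the 1e-3 tolerance the container asserts.

## Pseudo-bulk differential expression

UMI counts of each sample's cells within each cluster are summed when at
least 20 cells can be aggregated; a cluster is analyzable when at least 3
aggregates per condition remain. Genes enter the fit with CPM above 1 in at
least three aggregates and detection in at least 20 individual QC-passing
cells of the analyzed clusters. TMM factors are computed exactly as the
classic recipe prescribes (upper-quartile-closest-to-mean reference, M/A on
genes positive in both libraries, 30%/5% two-sided trims,
inverse-asymptotic-variance weights, geometric-mean-1 rescaling). Each gene
is fitted with a negative-binomial GLM, log link, offsets equal to log
effective library sizes (library size × TMM factor; a switch to raw
library sizes exists via the `tmm` argument), and design intercept +
condition. A single dispersion per cluster is estimated by maximizing the
Cox–Reid adjusted profile likelihood (subtracting half the log-determinant
of the weighted information per gene) with a 1-D bounded search; the
unadjusted profile maximum is biased low when two coefficients are fitted
to eight observations and would inflate the type-I error. Per-gene
coefficients are fitted by a vectorized IRLS with both coefficients clamped
to ±30 — for groups with all-zero counts the unconstrained MLE diverges in
the coefficients jointly while the fitted means stay finite — and the
condition effect is tested by a likelihood-ratio test against the
intercept-only model on χ²(1). BH adjustment and the gene-set test are both
applied within cluster, mirroring the cluster-stratified design.

The competitive gene-set statistic compares the mean signed z (signed
square root of the LRT statistic) inside a set with the mean outside; its
null variance `(1/m + 1/(G-m)) σ²` is inflated by `VIF = 1 + (m-1)ρ` with
ρ = 0.01, σ² estimated empirically from all tested genes, and only sets
with more than ten tested genes are considered. At ρ = 0 the procedure is
an exact two-sample z-test, and p-values are non-decreasing in ρ — under a
permutation null (where genes truly are exchangeable) the ρ = 0 statistic
is uniformly calibrated and any positive ρ is deliberately conservative.

At 4-vs-4 replicates with mean count 50 and dispersion 0.1, the asymptotic
z-value of a two-fold change is `log(2)/sqrt((1+φμ₀)/(4μ₀) + (1+φμ₁)/(4μ₁))
≈ 2.89`, bounding the power of any exact NB test at ≈0.82 for a two-sided
5% level; detecting two-fold changes reliably at that depth requires more
replicates or larger aggregates.

## The synthetic generator: what it emulates, and what it does not

`simulate_waterfall()` draws UMI counts as
`NB(mean = s_c · μ[g, pop(c)], dispersion = φ_g)` with log-normal size
factors (σ = 0.3, mean 1), five trajectory-ordered populations
(early/late monocytes, early/intermediate/mature macrophages at positions
0–1), and 4 control + 4 cKO samples of 400 cells — sizes chosen to match a
typical one-cartridge experiment of this kind. Structure comes from four
gene classes: per-population marker modules (40 genes, +3 log2 over
baseline, a third of the effect in trajectory neighbours so expression
changes smoothly), gradient genes whose log-means interpolate linearly
along the trajectory, on/off expression programs (half of the remaining
genes are ON only inside a random trajectory window and silenced 50-fold
elsewhere — this is what gives pseudo-bulk profiles their clearly bimodal
expressed/not-expressed structure), and a planted apoptosis module (the six
canonical symbols Bcl2l11, Casp3, Osm, Fos, Tnf, Fas plus generated
members, 2-fold up in cKO monocytes). The composition shift defaults to
control (0.15, 0.20, 0.20, 0.20, 0.25) vs cKO (0.30, 0.22, 0.20, 0.16,
0.12) over the five populations — cKO enriched at the start of the
trajectory and depleted at its end; no quantitative effect sizes are
published for this shift, so these are invented, documented defaults.
Dispersions decrease from 0.5 to 0.05 with gene mean, as in typical UMI
data. Planted QC failures (5% of cells: half tiny libraries, half ~15%
mitochondrial fraction) and hemoglobin-contaminated cells (1%) exercise
the QC stage; `simulate_reference()` derives monocyte/macrophage reference
profiles from the matched populations and gives dendritic/lymphoid/stromal
references independent expression programs.

The generator does **not** emulate ambient RNA, doublets, batch effects,
gene–gene correlation beyond the module structure, or read-level noise.
Tests passing on this generator therefore demonstrate the correctness and
calibration of the algorithms, not robustness to those artefacts in real
droplet data.

## Problem sizes used by the test-suite

The unit suite runs on a scaled-down design (8 × 120 cells, 1,000 genes —
kept well above the 399-feature QC threshold so clean cells are not
excluded wholesale); recovery, density and gene-set acceptance checks run
the full default design (8 × 400 cells, 2,000 genes) over ten seeds, and
calibration checks use 2,000-gene null simulations. These sizes are the
package's chosen trade-off between statistical resolution and a test suite
that runs in minutes on one core.

## Known limitations

* The dynamic cut is a simplified height-gap variant, not the full hybrid
  algorithm; deep, nested substructure may need `gap_factor` tuning.
* Marker detection is unmoderated; with very small clusters a moderated
  variance estimator would rank more stably.
* The common-dispersion NB model has no tagwise shrinkage; genes with
  atypical dispersion are tested slightly too liberally or conservatively.
* Fisher annotation assumes the reference and query share a gene universe;
  symbol mismatches silently shrink the universe.
* Paper-scale replication (gene/cell counts, nine clusters, 32 aggregates)
  requires the deposited accession data and is exercised only when a local
  copy is present.
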