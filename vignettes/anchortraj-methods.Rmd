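---
title: "Anchor-gene co-expression along aberrant differentiation trajectories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchor-gene co-expression along aberrant differentiation trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchortraj)
```

## The scientific problem

In fibrotic lung disease, alveolar repair can stall: transitional AT2 cells,
instead of completing differentiation into AT1 cells, accumulate in an
aberrant basaloid-like state (KRT5-/KRT17+ in human disease, Krt8+ ADI in
mouse injury models). A cytokine of interest — the *anchor gene*, IL11 in
the motivating analyses — is expressed specifically by these aberrant cells.
`anchortraj` packages the computational workflow needed to characterise such
an anchor from single-cell RNA-seq data:

1. quality control and library-size log-normalisation;
2. marker-based transcriptomic similarity between clusters (Jaccard index)
   and reference-to-query label transfer;
3. origin-rooted lineage inference over cluster centroids with per-cell
   pseudotime, and a spline test of anchor expression against pseudotime;
4. trajectory-restricted anchor co-expression module discovery with BH FDR,
   cross-dataset intersection, and network export;
5. expressing-cell enrichment and expression-level tests per cluster;
6. pseudobulk ranking, preranked permutation GSEA with leading-edge
   extraction, and binned-control signature scoring.

Every stage is validated against a bundled synthetic-data generator with
full ground truth, so each claim the pipeline makes on real data has a
measurable analogue on data where the answer is known.

## Statistical primitives

All rank-based statistics are centralised in a small set of primitives
(`spearman()`, `bh_fdr()`, `hypergeom_upper()`, `mann_whitney()`,
`ks_two_sample()`), each returning a one-row tibble. The variants are
pinned precisely because downstream thresholds depend on them:

* **Spearman** rho is the Pearson correlation of mid-ranks; the p-value
  uses the t approximation `t = rho * sqrt((n-2)/(1-rho^2))`. At the cell
  counts involved (hundreds per subset) the t approximation is accurate;
  an exact permutation variant would change nothing at the stated FDR
  thresholds.
* **FDR** is Benjamini–Hochberg throughout — the default of every tool in
  this analysis ecosystem.
* The **hypergeometric** enrichment p-value is the upper tail
  `P(X >= k)`, computed in log space via `phyper`; `k = 0` gives exactly 1.
* **Mann–Whitney** uses the exact permutation distribution when the pooled
  sample is tie-free and both groups are small (`max(n, m) <= 10`), and the
  normal approximation with tie and continuity correction otherwise; the
  `method` field records which branch ran.
* **Kolmogorov–Smirnov** p-values are asymptotic at effective size
  `nm/(n+m)`; small-sample exactness is checked in the test suite by
  permutation rather than shipped as a runtime branch.

The test suite pins each primitive to an independent brute-force oracle
(full enumeration of labelings for Mann–Whitney, a pmf-recurrence for the
hypergeometric, Pearson-on-midranks for Spearman, a hand-rolled step-up for
BH) to 1e-12.

## Quality control and normalisation

`qc_filter()` removes genes seen in fewer than 3 cells, then cells with
fewer than 200 detected genes, fewer than 500 UMIs, a complexity ratio
`log10(genes)/log10(UMI)` of 0.8 or less, or a mitochondrial fraction of
30% or more (case-insensitive `mt-` prefix, covering mouse and human symbol
dialects). Because removing cells can drop a gene below the 3-cell floor,
the two filters are iterated to a fixed point; this makes QC idempotent,
and the report records per-criterion removal counts under both filter
orders for transparency. `normalize_log()` computes
`ln(1 + 1e4 * count / total)`; natural log and the 1e4 scale are ecosystem
conventions, and every downstream statistic that matters (Spearman,
Mann–Whitney, KS) is invariant to this monotone choice.

## Trajectory model

`infer_lineages()` follows the origin-rooted lineage logic of
minimum-spanning-tree trajectory tools: cluster centroids in a
low-dimensional embedding, a Euclidean MST over centroids, and one lineage
per tree path from the designated origin to a leaf. `compute_pseudotime()`
replaces simultaneous principal curves with piecewise-linear centroid
paths: each cell on a lineage's clusters is orthogonally projected onto the
polyline and pseudotime is arc length from the origin centroid. The
terminal segment extends linearly beyond the last centroid so cells past
the terminus keep distinct pseudotimes (otherwise the curve end collects a
point mass that degrades spline fits); the origin end is clamped at zero.
This deterministic construction is validated on simulation: the correct
bifurcation is recovered in 20/20 default seeds and within-branch Spearman
correlation between pseudotime and true latent time is about 0.97.

`fit_pseudotime_gam()` regresses normalized expression on a cubic B-spline
basis of pseudotime (default 5 degrees of freedom, internal knots at
quantiles) and reports the F-test against the intercept-only model. The
Gaussian working model on log-normalized values is the field's standard
"GAM on processed expression"; a Monte-Carlo calibration test pins the
type-I error at alpha = 0.05 to [0.03, 0.07]. `anchor_trajectory_report()`
fits the anchor on every lineage and flags lineages with BH q < 0.05.
With two lineages and one true signal, the q-value of the null branch
equals its raw p-value, so the false-flag probability of the healthy
branch is the nominal 5% — a property worth remembering when interpreting
a single flagged run.

## Co-expression module discovery

Over a supplied cell subset (by default the disease-condition cells of the
aberrant lineage), `anchor_module()` correlates every candidate gene
(detected in at least 5% of the subset — a floor that merely excludes
near-empty vectors whose ranks are uninformative) with the anchor,
BH-adjusts, and keeps genes at FDR < 0.2. Two points deserve emphasis:

* **FDR 0.2 means one retained gene in five is expected to be noise.**
  On simulations with a planted 40-gene module, recall is ~0.99 and the
  realised false-discovery proportion averages ~0.23 — close to the
  nominal bound, which is the correct behaviour of BH, not a defect.
* **Intersection across datasets is the denoiser.** Running the module on
  two independently generated datasets and intersecting retains
  essentially only planted genes (precision ~1.0 in simulation), mirroring
  the motivation for requiring replication across cohorts.

`condition_correlation_comparison()` computes the per-gene anchor
correlations separately in two conditions and contrasts the two
correlation distributions with the two-sample KS test. One subtlety the
simulator exposed: the per-gene correlation estimates within one cell
subset are not independent — they share the anchor's sampled ranks — so
the KS null on random half-splits is mildly anti-conservative relative to
an iid assumption. At the default conditions the random-split mean p is
~0.4 (versus ~0.57 for truly iid samples at these sizes), which the
acceptance suite verifies.

`pathway_enrichment()` is a local hypergeometric over-representation test
against user-supplied GMT collections. The universe is the set of genes
actually tested during module discovery (a conditional-on-testing null),
not the whole genome; web-service enrichment tools use different
backgrounds, so p-values are comparable in spirit, not in digits.

## GSEA and signature scoring

`gsea_preranked()` implements weighted preranked GSEA: genes sorted by
decreasing statistic, hits add `|stat|^weight` normalised by the set
total, misses subtract `1/(N - N_hit)`, and ES is the signed
maximum-magnitude excursion (positive on magnitude ties). The null is
gene-permutation (random same-size sets), NES divides ES by the mean
|null ES| of matching sign, and the permutation p-value uses the
add-one-smoothed matching-sign count, so `p >= 1/(n_perm + 1)`. The
implementation is pinned exactly (double precision) to a brute-force
running-sum oracle and cross-checked against an independent library
implementation in the test suite. The leading edge is the set members at
or before the ES peak (at or after, for negative ES), exportable as a GMT
via `leading_edge_gene_set()` — the mechanism used to build de-novo
signatures from an enrichment result.

`module_score()` reproduces binned-control signature scoring: genes are
binned into 24 equal-frequency expression bins, each signature gene draws
100 controls from its bin (with replacement when bins run short;
`n_ctrl = NULL` takes whole bins, making the score exactly invariant to
constant shifts), and the per-cell score is the signature mean minus the
pooled-control mean. Scores are deterministic given a seed.

## The synthetic-data generator

`sim_config()` / `generate_dataset()` define the study conditions used for
validation. The generative model is negative binomial
(`Var = mu + mu^2/theta`, shared `theta = 2`) on top of a log-scale linear
predictor: per-gene baselines, per-cell log-normal library factors
(cv 0.3), cluster-specific DE effects, an anchor trend, and a latent
factor. The default layout is a bifurcation: a shared transitional origin
(30% of cells, latent time t in [0, 0.3]), a healthy branch through an
AT1 intermediate to AT1, and an aberrant branch through a basaloid
intermediate to a KRT5/KRT17-like terminus (20% + 20%).

Key planted structure, with the reasoning behind the frozen defaults:

* **Anchor** (`IL11`): baseline ~1.5 counts, log-linear trend of one
  two-fold change across the aberrant branch only.
* **Module** (40 genes): shares a standard-normal latent factor with the
  anchor in disease cells only (loading 1.15, zero in controls) — the
  mechanism behind the disease-specific correlation contrast. The factor
  multiplier is mean-centred (`E[exp(lf - l^2/2)] = 1`) so the coupling
  redistributes expression across cells rather than inflating the
  module's library share; without centring, the module's share of reads
  tracks the factor and induces spurious negative correlations across the
  entire background transcriptome (an effect we measured at a
  false-discovery proportion of 0.84 before adopting a 2000-gene panel
  with the module at ~1.5% of reads). Module baselines are heterogeneous
  (log-normal, sigma 1.2): real modules span expression levels, and the
  spread keeps the module's correlation distribution wider than the
  shared-anchor estimation noise. Module genes are uniformly elevated
  (x2^0.3) in disease cells as a disease-associated program.
* **Cluster markers**: 60 DE genes per cluster at log2FC 1.2 — many weak
  markers rather than few strong ones, which matches droplet data, powers
  kNN label transfer (accuracy ~0.96 at the default batch shift of
  sd 0.25 log2 per gene), and keeps per-window composition swings small
  enough not to confound the trajectory statistics.
* **Loading calibration**: the default loading was calibrated once on
  large simulations against a target mean anchor–module Spearman of 0.45;
  the frozen conditions deliver ~0.37, inside the +-0.10 calibration band.
  Pushing the mean higher requires loadings whose heavy tails destabilise
  the spline F-test and inflate the module false-discovery proportion, so
  the lower half of the band is the deliberate choice.

The 2-D embedding handed to the trajectory module is the simulator's own
noisy branch-unfolded layout (stem along x, branches at +-60 degrees,
Gaussian noise sd 0.05). This separates trajectory-algorithm testing from
preprocessing noise; `pca_embed()` output can be substituted for
end-to-end realism, at the cost of conflating the two error sources.

### What the simulation does not capture

Doublets, ambient RNA, UMI saturation, gene-length and GC biases,
cell-cycle structure, and realistic cluster imbalance are all absent.
Passing the validation suite therefore demonstrates that the algorithms
recover the planted statistical structure under NB noise, batch shifts and
compositional coupling — not that any particular real dataset satisfies
those assumptions.

### Known limitations of the frozen conditions

Three contract-level tensions surfaced during calibration and are worth
knowing about:

* At FDR 0.2, the module false-discovery proportion cannot fall much below
  0.2 when recall is complete; the ~0.23 observed is within a few false
  genes of the theoretical floor.
* An anchor trend strong enough to make the expressing-cell
  hypergeometric p-value smaller than 1e-6 in nearly every seed also
  correlates the anchor with trajectory-graded cluster markers and pushes
  the module false-discovery proportion past 0.3. The defaults favour the
  module criterion; anchor enrichment in the aberrant terminus is still
  decisive (p < 0.01 in ~19/20 seeds) but not astronomically so.
* The mean-centred latent factor imposes a Jensen penalty on disease-cell
  log-normalized means, so the planted module's *signature score* in
  aberrant disease cells separates from control cells but is not
  guaranteed to exceed them in sign; the raw-count elevation is positive
  by construction.

## Numerical and degenerate-input policy

Constant expression vectors are rejected by `spearman()` (undefined
correlation) and skipped per-condition by the KS comparison (an error only
when more than half the module is undetected). Empty marker sets warn
rather than error, and the Jaccard index of two empty sets is defined as 0
with a warning. PCA components follow a deterministic sign convention
(largest-magnitude loading positive), MST ties resolve by lexicographic
cluster order, GSEA magnitude ties resolve positive with a 1e-12
tolerance, and every stochastic step (simulation, GSEA permutations,
control-gene sampling) flows from an explicit integer seed.

## Problem sizes used in validation

The acceptance suite runs the generator at its default size (2000 genes x
2000 cells) across 20 seeds for trajectory, spline-flag and module
criteria, 50 seeds for the condition-contrast calibration, and 10 paired
datasets for label transfer; oracle-equivalence sweeps cover every
feasible hypergeometric configuration up to N = 60, all Mann–Whitney
shapes up to n + m = 10, and 1000 random rankings for the GSEA running
sum. These sizes were chosen so the full suite exercises every stated
property at the study conditions while remaining comfortably runnable on a
laptop.
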