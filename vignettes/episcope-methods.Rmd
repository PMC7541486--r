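---
title: "Scoring disease impact across neuronal subtypes: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring disease impact across neuronal subtypes: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

episcope quantifies how strongly each transcriptomic cell subtype is
affected by a disease condition in an annotated case/control single-nucleus
RNA-seq cohort, and finds condition-associated co-expression programs. This
vignette explains the statistical machinery, the tunable parameters and
their defaults, what the synthetic cohort generator does and does not
emulate, and the design decisions taken where the problem was genuinely
open.

## The expression-similarity score

The central question — "how different is this subtype between cases and
controls, relative to its natural between-donor variability?" — is answered
in a reduced expression space. All cells of all samples are total-count
normalized (default scale 10,000 counts per cell, no log transform before
PCA; both are config switches) and jointly reduced by PCA to 100
components. For each subtype $t$ and sample $s$ the centroid
$\bar v_{t,s}$ is the mean of the sample's cells in PC space; centroids
need at least 5 cells. All pairwise Pearson correlations between a
subtype's sample centroids are computed over the PC coordinates,

$$c_{t,s_i,s_j} = \mathrm{cor}(\bar v_{t,s_i}, \bar v_{t,s_j}),$$

and the control–control correlations provide a robust baseline: their 40%
trimmed mean $m_t$ (trimming 40% from *each* tail, the convention of R's
`mean(trim=)`; with fewer than one value left the median is used) and
their MAD $\sigma_t$ (scaled by 1.4826 for normal consistency, R's
`mad()` default; both conventions are exposed as arguments). Every
(control, case) centroid pair is then standardized,

$$z_{t,s_i,s_j} = \frac{c_{t,s_i,s_j} - m_t}{\sigma_t},$$

so $z \approx 0$ means the case profile sits inside the control cloud and
negative $z$ means condition-driven divergence. A subtype needs at least 3
control samples with centroids; a zero or undefined MAD flags the subtype
as degenerate rather than producing infinite scores.

The per-subtype distribution of $z$ over all (control, case) pairs is
summarized by quartiles and classified ordinally: upper quartile below
zero → *affected* (1); additionally median below the class-wise median of
medians → *highly affected* (2); the lowest median per class (principal
and interneuron separately) is the single *top-1* (3), assigned after the
other rules and overriding them.

Under the null the score is centered but not variance-1: the MAD of a
handful of control pairs is noisy, so individual cohorts can show
|median z| above 0.5 for some subtype. The calibration property the tests
assert is therefore the centering — across replicate null cohorts at the
study's replication (10 control, 9 case donors), each subtype's median
score stays within 0.5 of zero.

## Pseudobulk differential expression and its post-filters

Counts are summed per (sample, gene) within a subtype and tested with a
negative-binomial GLM per gene — median-of-ratios size factors, trended
dispersion shrinkage, Wald test (DESeq2 under the hood, positive fold
changes meaning higher in cases). Testing samples rather than cells
respects the donor as the unit of replication; at least 2 samples per
condition are required. Genes are called at |Z| > 3 (strict) and must
additionally show distinct expression — a raw count above 1 UMI in at
least 5% of the subtype's cells. The union of expressed genes over all
subtypes is the background universe for every enrichment test.

Fisher enrichment of the DE genes in curated lists (GWAS hits, curated
epilepsy genes) reports the conditional maximum-likelihood odds ratio $h$
with its exact 95% CI (`fisher.test`); an independent noncentral-
hypergeometric grid scan backs this in the tests. Ordinal categories:
$h > 1$ affected, CI lower bound $> 1$ highly affected, largest $h$ per
class top-1.

Because the number of DE genes grows roughly linearly with the number of
cells observed (and the number of enriched GO terms with the number of DE
genes), raw counts are not comparable across subtypes. Both counts are
therefore regressed on their driver by M-estimation with Huber loss
(tuning constant 1.345, `MASS::rlm`, convergence 1e-8; an exact linear
relation short-circuits to least squares since the M-scale collapses), and
the residuals carry the signal: positive → affected, above the 75th
percentile of the affected residuals (linear-interpolation percentile,
a documented choice) → highly affected, largest per class → top-1.

## GO-term machinery

Over-representation of each term in each subtype's DE genes is a one-sided
hypergeometric test against the shared universe, BH-adjusted within
(subtype, namespace), retained at adjusted p ≤ 0.05. Terms whose enriched
genes are >20% autopsy-associated are removed as postmortem artifacts.

Two clustering stages reduce redundancy. Within a subtype, terms are
clustered on the Jaccard distance of their enriched gene sets (complete
linkage — the `hclust` default, since no method is prescribed — cut at
0.66). Across subtypes, the distance between two terms is the fraction of
subtypes, among those where both are enriched, that placed them in
different within-subtype clusters; terms never co-enriched together get
distance 1 (a documented choice — the quantity is otherwise undefined).
Average-linkage clustering cut at 0.66 merges terms the subtypes agree on;
each collapsed cluster is named by its member with the least mean log10
adjusted p.

For visualization, the (cluster × subtype) matrix of minimal −log10
adjusted p values is trimmed at 10, L1-normalized per row (the stated
distance is L1, so L1 normalization is the consistent reading of
"row-normalized"), Ward-clustered and cut at 2.5; row groups of at least 5
clusters are kept. (Subtype, cluster) pairs are embedded in 2D by UMAP on
pairwise Jaccard distances of their enriched-gene unions (k = 10
neighbors, spread 1.5, min_dist 0.2, fixed seed, single-threaded so
coordinates are reproducible).

Subtype relatedness uses a weighted Jaccard over enriched pathways. The
weight of pathway $i$ in subtype $k$ is the inverse of the summed Jaccard
similarities of its gene set to all of $k$'s enriched pathways *including
itself*, which bounds weights in (0, 1] and makes them well-defined; a
pathway absent from a subtype contributes weight 0. Similarity is
$\sum_i \min(w_{k,i}, w_{l,i}) / \sum_i \max(w_{k,i}, w_{l,i})$, clustered
at cut height 1.2 (average linkage, chosen for consistency with the
cross-subtype stage; the method is not prescribed).

## Composition testing

Within-sample subtype proportions are compared between conditions with a
permutation test over sample labels — the sample, not the cell, is the
exchangeable unit. The statistic is the absolute difference of
condition-mean proportions (the simplest statistic exchangeable under the
scheme; a studentized variant would be a drop-in). p uses the add-one
estimator $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$, never zero;
small cohorts can enumerate all label assignments exactly. The p value is
used as a continuous measure, not a verdict: < 0.2 affected, < 0.05 highly
affected, smallest per class top-1.

## The six-metric impact score

Each metric maps subtypes to ranks 0–3 with exactly one top-1 per class;
the total is the weighted sum with a-priori weights: expression similarity
1.0 (the direct measure), composition 0.66, GO-term count 0.66, GWAS
enrichment 0.66, curated epilepsy genes 0.33 (literature-biased), DE-gene
count 0.66. All ties (top-1 assignment, final ordering) break
deterministically by subtype name and the aggregate is monotone in every
rank. Subtypes for which a metric cannot be computed (no DE genes,
degenerate similarity baseline) rank 0 on that metric rather than
propagating missingness.

## Consensus co-expression modules

Within a cell family (level-2 cluster), genes seen in fewer than 20 cells
are dropped; the rest are centered, scaled and ranked by their largest
absolute PCA loading over 120 components, keeping the top panel (5,000 at
full scale; the desk-scale analyses here use 300–400 of 500 synthetic
genes, chosen so planted module members survive selection the way
well-measured genes do in real panels).

The network is a signed-hybrid adjacency $a = \mathrm{cor}^\beta$ for
positive correlations, 0 otherwise. $\beta$ is scanned over 1…30: powers
with mean connectivity at or above the 95th percentile are discarded and
the lowest surviving power with scale-free fit $R^2 \ge 0.93$ is chosen,
falling back to the best-fitting power. The unsigned topological overlap

$$\mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
{\min(k_i, k_j) + 1 - a_{ij}}$$

is computed on each of 100 resamples of two-thirds of the cells (20
resamples at desk scale) and aggregated element-wise at the 0.5 quantile;
the consensus is taken over TOM rather than adjacency (the more robust of
the two readings of a consensus network). Genes with zero variance in any
resample are dropped.

Modules come from average-linkage clustering of 1 − TOM with a
dynamic-hybrid-style cut implemented as a scan: because powered TOM
distances compress into a narrow band near 1, cut heights are expressed
relative to the dendrogram's height range; the scan keeps the level
exposing the most cores of ≥ 15 genes (ties to the tightest level) and a
PAM-like stage then assigns leftover genes to the module with the highest
mean TOM, admitted when their connectivity is nearer, on a log scale, to
the members' than to the background's. Two cohesion guards reject loose
pseudo-modules of mutually unconnected genes (sequencing-depth and
compositional covariation produce them): a core's mean within-TOM must
exceed its mean TOM to the remaining genes by a factor of 30, checked both
at detection and after PAM growth — genuine modules sit 2–8 orders of
magnitude above background after powering, depth blobs about one.

Refinement operates on intramodular connectivity,
$k_{IM}(g, M) = \sum_{m \in M, m \ne g} \mathrm{TOM}(g, m)$, computed on
the consensus TOM so one matrix drives detection, merging and
reassignment: modules whose $k_{IM}$ vectors correlate at ≥ 0.85 merge
(transitively); genes move to another module when its $k_{IM}$ exceeds
1.25× the current one, iterating with recomputation until stable (cap 50
passes); finally each gene's $k_{IM}$ is tested against the empirical
distribution of non-members' $k_{IM}$ to that module (one-sided normal
location test — the published description of this pruning step is not
detailed enough to recover the exact test, so this interpretation is
explicit), BH-adjusted at 0.05.

The filter cascade is order-dependent and fixed. (i) Overlap: a module
with ≥ 75% of its genes inside a larger module, and a weighted Pearson
correlation ≥ 0.75 between the two $k_{IM}$ vectors (weights concentrate
on the union's members, smoothed by $k_{IM}$ magnitude; plain Pearson is a
config fallback), is removed. (ii) Injury: the dot product of member
$k_{IM}$s with −log10 injury/postmortem DE p values is compared against a
null from re-drawing the member gene labels (10,000 replicates at full
scale); p < 0.05 removes the module. (iii) Sample confounding: per-cell
module expression — the $k_{IM}$-weighted (weights scaled to sum 1) sum of
per-gene z-scored expression — is fit against each single-sample indicator
and against condition; if any sample indicator explains more variance, the
module goes. (iv) Only modules with a significant condition coefficient
(two-sided, 0.05) survive, reported with CI. The per-cell significance
test inherits the usual caveat of cell-level models: cells within a donor
are correlated, so p values are anti-conservative; the sample-confounding
filter is the counterweight, and on synthetic data an occasional
uncoupled module passes (iv) — visible in the demo run.

Curated-list enrichment in a module ranks all genes by $k_{IM}$ and tests
whether curated genes sit near the top with a Wilcoxon rank-sum statistic
whose variance is inflated by $\mathrm{VIF} = 1 + (m - 1)\bar\rho$, where
$\bar\rho$ is the mean pairwise expression correlation of the $m$ curated
genes present (floored at 0) — shared co-expression otherwise overstates
significance. Bonferroni across tested modules.

## smFISH intensity normalization

Raw integrated densities of a target and a reference channel are log2
transformed; the reference (whose expression is condition-independent by
design) is quantile-normalized across tissue sections on the log2 scale —
the reference distribution is the mean of the per-section quantile
functions at mid-rank probabilities, so equal-size sections end up with
identical sorted values — and the target is corrected on the raw scale by
the factor reference_normalized / reference. Applying the normalization on
the log scale and the correction on the raw scale is the internally
consistent reading of the procedure and is flagged as an interpretation;
the correction is invariant to joint rescaling of both reference channels.
Cells with non-positive reference signal are excluded rather than
producing infinities. Group comparisons are one-sided: Welch's t with
Satterthwaite degrees of freedom, or Mann–Whitney (exact for groups ≤ 20
without ties, else normal approximation with tie correction); constant
pooled values return p = 1 with a flag.

## The synthetic cohort generator

The generator emulates the cohort structure the pipeline targets: ~10
control and ~9 case donors, 20–40 subtypes on a fixed four-level hierarchy
split into principal and interneuron classes (names echo cortical
nomenclature purely for readable reports), negative-binomial counts via a
gamma–Poisson mixture with dispersion shared across genes by default
(variance $\mu + \phi\mu^2$, $\phi = 0.4$), log-normal library sizes
(meanlog log 2000, sdlog 0.3 — shallow snRNA-seq depth), and per-subtype
expression programs (10% marker genes with log-normal multipliers, log-sd
0.8) that separate subtypes in PCA space. Planted truth: condition effects
(chosen subtypes, n genes at ±|log2FC|, half up half down), composition
shifts (case expectation multiplied per subtype), and co-expression
modules driven by a per-cell log-normal latent factor scaling member-gene
means multiplicatively — positive correlation structure detectable by TOM
without materially changing marginal means. Member genes load the factor
with individual exponents (uniform 0.6–1.4), giving the hub-and-periphery
connectivity spectrum real modules show, and are drawn from the
better-expressed half of the panel since latent-factor co-expression is
unobservable for genes with a handful of counts. A factor log-loading of
1.2 yields within-module Pearson correlations near 0.5 on normalized
log counts. Condition coupling shifts the factor's log-mean in case cells.

One global seed drives independent per-stage, per-(sample, subtype)
substreams, so the same configuration regenerates bit-identically and
adding cells to one sample never perturbs another.

The generator deliberately omits ambient RNA, doublets, batch chemistry,
and annotation errors; the cell-count distribution per (sample, subtype)
is Poisson around a configurable mean because no particular distribution
is prescribed beyond coverage requirements. Passing tests therefore show
the statistics behave as specified on clean, correctly annotated data —
they do not certify robustness to the QC failures real pipelines face
upstream.

## Problem sizes and numerical choices

The bundled analyses and tests run at desk scale as the package's own
choice of problem size: cohorts of 19 samples, 24 subtypes, 500 genes for
the end-to-end demo; 300-gene, ~1,000-cell, 20-resample networks for
module recovery; 200 replicate mini-cohorts for null calibration of the
composition test. Determinism is absolute: every stochastic stage takes a
seed, the consensus resampler and permutation tests use derived
substreams, and UMAP runs single-threaded.

Degenerate inputs are handled explicitly rather than silently: all-zero
cells fail normalization with the offending cells named; zero-variance
PCA input errors; degenerate similarity baselines are flagged and excluded
from classification; empty list∩background enrichments return an
undefined odds ratio with a flag; constant robust-regression predictors
error; ties in every top-1 assignment break by subtype name and are
reproducible.
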