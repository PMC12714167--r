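---
title: "Methods: controllability, differential circuits, and regional transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: controllability, differential circuits, and regional transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: the models, the
tunable parameters and why they default to what they do, what the
synthetic-data generators emulate (and what they deliberately do not),
the numerical choices, and the known limitations.

## Average network controllability

A subject's structural connectome is a symmetric, nonnegative,
FA-weighted adjacency matrix $A$ over a named parcellation. We model
regional activity with discrete, noise-free, linear time-invariant
dynamics

$$x_{t+1} = A\,x_t + B_k u_t,$$

where $B_k = (e_{k_1}, \dots, e_{k_p})$ selects control regions. The
package works node-wise ($p = 1$, $B = e_k$): per-region values are what
group comparisons consume. Average controllability of node $k$ is the
trace of the infinite-horizon controllability Gramian

$$W_k = \sum_{t \ge 0} A^t e_k e_k^\top (A^\top)^t, \qquad
  a_c(k) = \operatorname{trace}(W_k) = \sum_{t\ge0} \lVert A^t e_k \rVert^2 \ge 1,$$

the unique solution of the discrete Lyapunov equation
$W = A W A^\top + e_k e_k^\top$.

**Stabilization.** The series converges only for spectral radius below
one, which raw FA matrices do not satisfy. `stabilize()` divides by
$1 + \lambda_{\max}(A)$, the dominant convention of the network-control
literature. This choice changes *absolute* $a_c$ values — only contrasts
and rankings are comparable across conventions — and pre-scaling the raw
matrix by a constant shifts the overall gain (the two stabilized
matrices are proportional, not equal), so the package never interprets
absolute magnitudes.

**Numerics.** `average_controllability()` solves the Lyapunov equation
by the doubling iteration $W \leftarrow W + M W M^\top$,
$M \leftarrow M^2$ to an elementwise tolerance of $10^{-12}$ (quadratic
convergence for stable $A$). `average_controllability_all()` exploits
symmetry: with $A = V \Lambda V^\top$,
$a_c(k) = \sum_i V_{ki}^2 / (1 - \lambda_i^2)$, so one
eigendecomposition yields all regions. The test suite holds both routes
to the truncated series $\sum_{t=0}^{1000}\lVert A^te_k\rVert^2$ within
$10^{-8}$.

Group comparison (`compare_anc()`) gates each region on per-group
Shapiro–Wilk normality at $\alpha = 0.05$ (every group must pass),
then runs one-way ANOVA or Kruskal–Wallis, pairwise post hocs only
where the omnibus is significant, and Benjamini–Hochberg across
regions. The gate's $\alpha$ and its all-groups-pass aggregation are
package conventions; the analysis this emulates states the gate but not
its details.

## Differential subnetworks (network-based statistic)

For a two-group contrast, a pooled-variance two-sample $t$ is computed
at every upper-triangle edge; edges with zero pooled variance (absent
in all subjects) are untestable and carry $t = 0$. Edges passing the
primary threshold (two-sided $p < 0.001$ uncorrected, the conventional
component-forming threshold) form a graph whose connected components
are the candidate subnetworks. Component *size* is its edge count
(extent); intensity-weighted variants are out of scope. Familywise
error control comes from the permutation null of the maximum component
size: group labels are reshuffled uniformly (the observed labelling is
never counted among the permutations) and each observed component gets

$$p_{\text{FWER}} = \frac{1 + \#\{b : \max\text{-size}_b \ge s_{\text{obs}}\}}{n_{\text{perm}} + 1},$$

which is valid and never zero; the smallest attainable value is
$1/(n_{\text{perm}}+1)$. The default 5000 permutations matches the
emulated analysis; calibration and power tests use 500–1000 to keep
runtimes in seconds (problem sizes below).

The clinical contrasts are built by `circuit_contrast()`: the SI
(suicidal ideation) circuit compares patients with vs without SI; the
SB (suicidal behavior) circuit compares SB patients against the merged
non-SB patients (MDDNSI ∪ MDDSI). Healthy controls take part in
neither circuit contrast. Behavioral relevance of a detected component
is assessed by partial correlation of its per-subject mean FA strength
with scale scores, residualizing both on age, sex (coded 0/1),
education, and medication load, with Bonferroni correction across the
scale battery.

## Regional expression and its preparation

The expression input is a genes × regions matrix in the style of a
donor-microarray brain atlas. The preparation chain mirrors the
standard processing steps at gene level (probe-level steps are outside
the input boundary):

* **Assignment** — each tissue sample goes to its nearest region
  centroid if within 2 mm (Euclidean); exact ties break to the lower
  region index, deterministically.
* **Normalization** — scaled robust sigmoid per gene within donor:
  $s = (1 + \exp(-(x - \mathrm{med})/(\mathrm{IQR}/1.35)))^{-1}$,
  min–max rescaled to $[0,1]$. IQR/1.35 approximates a robust standard
  deviation; constant genes map to 0.5. The transform is
  rank-preserving, so downstream correlation structure survives.
* **Consistency filtering** — a gene's differential stability is the
  mean pairwise Spearman correlation of its per-donor regional
  profiles; genes below 0.1 are dropped. The threshold is a package
  default (the emulated analysis does not state one) and is exposed in
  the configuration. Note that with only two donors the DS null sd at
  100 regions is ≈ 0.1, so noise-gene removal is only ~84% there;
  with six donors (the default) it exceeds 95%.
* **Aggregation** — region value = mean over assigned samples pooled
  across donors; regions without samples are kept as explicit `NA`
  columns, never zero-filled, and excluded pairwise downstream.

## Coexpression modules over regions

Samples are *regions*, genes are variables. The network is unsigned:
$a_{ij} = |\mathrm{cor}(g_i, g_j)|^\beta$. The topological overlap

$$\mathrm{TOM}_{ij} = \frac{\sum_{u \ne i,j} a_{iu}a_{uj} + a_{ij}}
 {\min(k_i, k_j) + 1 - a_{ij}}, \qquad k_i = \sum_{j \ne i} a_{ij},$$

gives the clustering dissimilarity $1 - \mathrm{TOM}$. Modules come
from average-linkage hierarchical clustering with a simplified cut:
a static height cut at 0.99 with deep split off, clusters under the
minimum module size (default 100 genes) merged into the grey
background, followed by fusion of modules whose eigengenes are closer
than 0.25 in correlation dissimilarity. This is deliberately simpler
than the full dynamic hybrid tree cut; the planted-partition recovery
tests gate its adequacy (adjusted Rand index ≈ 1 on the fixtures).

**Soft power.** The default is $\beta = 12$, the value the demo
configuration records and a conventional choice for unsigned networks.
`select_soft_power()` implements scale-free topology selection —
smallest power whose signed log–log degree-distribution fit reaches
$R^2 \ge 0.85$, else the best-fitting power with a warning — and is the
right tool for transcriptome-scale data with heavy-tailed
connectivity. It is *not* applied by default because the package's
block-correlated synthetic fixtures are intentionally low-rank: their
degree distribution is bimodal, never scale-free, and the selection
rule then degenerates to the largest candidate power, at which
within-module TOM dissimilarity exceeds the 0.99 cut and no modules
survive. On such data a fixed conventional power is the statistically
sound choice; pass `power = NULL` to opt into selection on real data.

Module eigengenes are first principal components of the per-gene
standardized module submatrix (SVD), sign-oriented so the mean
correlation with member genes is positive. Module–trait association is
Pearson $r$ with BH-FDR across all module × trait cells. Hub genes
satisfy $|\mathrm{MM}| > 0.8$ and $|\mathrm{GS}| > 0.5$ (module
membership = correlation with the own-module eigengene; gene
significance = correlation with the trait).

**The regional trait.** The emulated analysis never states the
per-region trait used for module–trait correlation. The package's
default is the per-region sum of $|t|$ over the significant NBS
component's incident edges, zero elsewhere — a continuous "circuit
involvement" map. When no component is significant (null runs) the
fallback uses all edges' $|t|$, so the module–trait stage still runs
and can be calibrated. Binary membership or an ANC-difference map are
reasonable alternatives a user can substitute by passing any trait
vector.

## Enrichment

**Over-representation** is the hypergeometric upper tail
$P(X \ge k)$ for an overlap of $k$ list genes with a term, with the
reporting filters $p < 0.01$, overlap ≥ 3, enrichment factor
$(k/n)/(K/N) > 1$, and a top-5 reporting mode. The universe defaults
to the genes of the expression matrix (the coexpression background),
not the genome.

**Cell-type enrichment** row-normalizes a genes × cell-types
mean-expression reference to specificities $s_{gc}$ (rows sum to 1)
and bootstraps the mean specificity of the target list against
uniformly drawn background lists of the same length:
$p_c = (1 + \#\{\bar{s}_{\text{boot}} \ge \bar{s}_{\text{obs}}\})/(B+1)$,
with a sd-from-mean $z$ and BH-FDR across cell types. Sampling is
uniform — no expression-level matching of bootstrap lists — a
documented simplification; the bootstrap count and background
definition are package defaults (1000; all reference genes).

**Validation** emulates an independent two-group expression study:
per-gene two-sample tests (t or rank-sum by the same normality gate) at
$p < 0.05$, intersection of the DEG set with the hub genes, and
diagnostic performance of overlap genes by the rank-statistic AUC
$U/(n_1 n_0)$ with ties counted ½.

## What the generators emulate — and what they do not

Every pipeline input is synthetic with planted, recoverable structure;
generators are pure functions of (spec, seed) and serialize their
ground truth as JSON sidecars so tests never re-derive it.

* **Connectomes** — random geometric graph on uniform centroids in a
  100 mm cube, ~15% density, distance-decaying mean FA in [0.2, 0.8],
  subject-level Gaussian edge noise (sd 0.1), clipped to [0, 1]. The
  planted differential component is forced into the topology at
  mid-range mean weight (so clipping cannot bias the planted contrast)
  and attenuated by `edge_effect × noise_sd` in the affected group.
  Cohort sizes default to 37/31/34/22 (HC/MDDNSI/MDDSI/MDDSB), the
  clinical group sizes this pipeline emulates; parcellations default
  to 90 regions to keep desk-scale runtimes. Phenotype scales are
  Gaussian fixtures whose group locations follow the published
  clinical pattern — they are fixtures, not estimates. Not emulated:
  diffusion signal, streamline counts, spatial autocorrelation of
  noise, hemispheric structure.
* **Expression** — block-correlated modules: module $m$ has a latent
  regional factor $f_m = \rho\,z(\text{trait}) + \sqrt{1-\rho^2}\,\varepsilon$
  and members $\sqrt{w} f_m + \sqrt{1-w}\,\eta$, so within-module
  correlation is $w$ and the eigengene–trait correlation is $\rho$ by
  construction (gene-level GS is $\sqrt{w}\rho$ — at $w = 0.7,
  \rho = 0.5$ no gene can clear the GS > 0.5 hub threshold, which is
  why the demo configuration plants $w = 0.8, \rho = 0.7$).
  Background genes are independent noise. Not emulated: regulatory
  structure beyond block correlation, heavy-tailed connectivity,
  spatial expression gradients.
* **Cell-type reference** — per-gene baseline (lognormal) times mild
  lognormal noise across types; the enriched module's genes are
  multiplied by the fold in one type, giving expected specificity
  fold/(fold + C − 1) there.
* **Validation set** — unit-variance Gaussian genes with planted mean
  shifts; a two-group design only.

Passing tests therefore demonstrate correctness and calibration of the
machinery on data satisfying these generative assumptions — not
performance on real connectomes or microarray data, whose noise is
heavier-tailed, spatially structured, and batch-confounded.

## Problem sizes and runtime choices

The test and acceptance workloads use 90-region, 15–20-subject-per-arm
cohorts with 500–1000 permutations, 1000-gene expression fixtures over
120 regions, and 200–1000 bootstrap draws; null calibrations use
100–200 simulated datasets and 20 end-to-end null runs. These sizes
make every Monte-Carlo bound testable in seconds to a few minutes per
block while leaving the estimators' behavior representative; all are
configuration values a user can raise.

## Null-calibration semantics

With all planted effects zero, each detector (NBS per contrast,
module–trait FDR, cell-type FDR) is nominally 0.05-level, so over 20
null seeds a detector is *expected* to fire occasionally; the
end-to-end null check therefore bounds each detector's firing fraction
by the binomial 95% Monte-Carlo envelope of the nominal rate (at most
3 of 20), rather than demanding literally zero findings.

## Known limitations

* The tree cut is a simplified static rule; on real data with nested
  or unbalanced modules the full dynamic hybrid cut will split
  branches this rule merges.
* Edgewise NBS tests are raw group differences; covariate-adjusted
  edgewise GLMs are out of scope.
* EWCE's uniform bootstrap ignores expression-level matching, which on
  real references inflates enrichment of highly expressed gene sets.
* Absolute controllability values are convention-dependent
  (stabilization); only contrasts are meaningful.
* The chi-square routing reproduces the printed gender-table statistic
  (≈ 4.85, df 3, p ≈ 0.18); the package makes no attempt to reconcile
  differently printed categorical p-values in the emulated analysis.
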