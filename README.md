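# ctrlcircuit

Linking structural brain-network controllability to regional gene
expression in depression subgroups with suicidal ideation (SI) or
suicidal behavior (SB). The package is an end-to-end, fully tested R
re-implementation of that analysis chain, exercised on synthetic data
with planted, recoverable ground truth — for methodologists who want
the machinery (and its calibration) without access to subject-level
imaging or donor microarray data.

## What it computes

**Average network controllability.** Each subject's FA-weighted
connectome `A` (symmetric, nonnegative, zero diagonal) drives discrete
linear dynamics `x[t+1] = A x[t] + B_k u[t]`. After stabilization
(`A / (1 + λ_max)`), the per-region average controllability is the
trace of the infinite-horizon controllability Gramian

    W_k = Σ_{t≥0} A^t e_k e_k' (A')^t ,   a_c(k) = trace(W_k) ≥ 1,

solved from the discrete Lyapunov fixed point `W = A W A' + e_k e_k'`.
Group differences per region use a Shapiro–Wilk-gated ANOVA /
Kruskal–Wallis with BH-FDR and post hocs.

**Differential subnetworks (NBS).** Edgewise two-sample t-tests, a
primary threshold (two-sided p < 0.001), connected components of the
suprathreshold graph, and familywise error control from the
permutation null of the maximum component size:
`p_FWER = (1 + #{perm max ≥ observed}) / (n_perm + 1)`. The SI circuit
contrasts patients with vs without suicidal ideation; the SB circuit
contrasts SB patients with the merged non-SB patients.

**Coexpression modules over brain regions.** Unsigned adjacency
`|cor|^β` (default β = 12), topological overlap, average-linkage
clustering with a minimum module size of 100, module eigengenes,
module–trait Pearson correlations with BH-FDR against an NBS-derived
circuit trait, and a hub screen at |MM| > 0.8 and |GS| > 0.5.

**Enrichment and validation.** Hypergeometric over-representation
(filters p < 0.01, overlap ≥ 3, enrichment factor > 1), bootstrap
expression-weighted cell-type enrichment, and validation of hub genes
against an independent two-group expression set (DEG overlap +
rank-statistic ROC/AUC).

**Synthetic data.** Generators for every input — group-structured
connectomes with a planted differential component, regional expression
with planted modules and trait couplings, cell-type references with
planted specificity folds, validation sets with planted effect sizes —
each writing a JSON ground-truth sidecar.

## Worked example

```r
library(ctrlcircuit)

# a small closed form: one node coupled at 0.5 to a second node
average_controllability(matrix(c(0, 0.5, 0.5, 0), 2), k = 1)
#> [1] 1.333333    # = 4/3, the hand-solved Lyapunov trace

# the full synthetic pipeline (500 permutations for a quick run)
res <- run_pipeline(pipeline_config(seed = 11, nbs = list(n_perm = 500)))
print(res)
```

```
ctrlcircuit pipeline run (seed 11)
Cohort: 124 subjects, 90 regions

Network-based statistic (SI contrast)
  primary threshold p < 0.001  |  500 permutations
  component 1: 10 edges over 11 nodes, mean t -8.92, FWER p = 0.001996 *
  component 2: 1 edges over 2 nodes, mean t -4.09, FWER p = 0.4391
  component 3: 1 edges over 2 nodes, mean t +3.84, FWER p = 0.4391
Network-based statistic (SB contrast)
  primary threshold p < 0.001  |  500 permutations
  component 1: 1 edges over 2 nodes, mean t +4.18, FWER p = 0.4411
  component 2: 1 edges over 2 nodes, mean t +3.80, FWER p = 0.4411

ANC regions with group differences (FDR < 0.05): 2 of 90

Coexpression modules (soft power 12)
  modules: blue(150) brown(150) turquoise(150) yellow(150)
  background (grey): 400 genes
  trait-associated modules (FDR < 0.05): turquoise (r = 0.64)
  hub genes: 146
EWCE enriched cell types: GABAergic
Validation overlap genes: GENE00002, GENE00003, GENE00004, ...
AUC: GENE00002 0.92, GENE00003 0.91, GENE00004 0.68
```

Reading the output: the planted 10-edge SI component is recovered
exactly (negative mean t = reduced connectivity in the SI group) and
survives FWER correction, while the stray single-edge components do
not; the four planted coexpression modules are recovered with their
sizes; the trait-coupled module is flagged by FDR, its hub genes are
enriched in the planted GABAergic reference, and the planted
differentially expressed genes reappear as hub–DEG overlaps with high
AUC. `res$report$recovery` holds the quantitative ground-truth
comparisons (edge-set Jaccard, adjusted Rand index, estimated
module–trait r).

A YAML configuration equivalent to the defaults ships at
`inst/extdata/demo-config.yaml`
(`run_pipeline(load_pipeline_config(...))`).

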