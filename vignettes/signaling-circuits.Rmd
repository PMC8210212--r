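---
title: "Mechanistic signaling-circuit analysis of single cells: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mechanistic signaling-circuit analysis of single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sccircuits)
```

# The model

## Circuits

A signaling pathway is a signed directed graph whose nodes carry one or
more gene products (a node with many genes models a family of proteins
sharing one signal-transduction role, e.g. the set of growth-factor
ligands feeding one receptor). The functional unit is the **circuit**: for
each effector node, the sub-network of all routes from any receptor to
that effector. `extract_circuits()` takes receptors and effectors from
curated `is_receptor`/`is_effector` annotations when the node table has
them, and otherwise from topology (sources and sinks).

On acyclic graphs the circuit's member set equals the union of nodes over
all simple receptor-to-effector paths, and the test suite verifies this
against an exhaustive path enumerator. On cyclic graphs "union of paths"
is ambiguous, so membership is defined as the reachability intersection —
nodes reachable from some receptor *and* co-reachable to the effector —
which coincides with the path union on DAGs and is the standard
generalization. Edges are the induced edges among members.

## Signal propagation

Each node's normalized expression $v_n \in [0,1]$ gates the signal flowing
through it:

$$S_n = v_n \cdot \Big(1 - \prod_{s_a \in A}(1-s_a)\Big) \cdot
        \prod_{s_i \in I}(1-s_i).$$

Three conventions close the recursion, all configurable but fixed by
default:

* **Receptors** receive one implicit activation of 1, so
  $S_{\text{receptor}} = v_{\text{receptor}}$ (times any inhibitory
  factors). Without this, every source node would compute an empty
  activation product and the whole circuit would be silent. Whether the
  original formulation seeds receptors with 1 or with the node value on a
  virtual incoming edge is not observable from the formula alone; the
  convention used here is documented, not claimed equivalent.
* A node whose in-circuit inputs are **only inhibitory** uses activation
  factor 1 (it is constitutively on, dampened by its inhibitors).
* **Multi-gene nodes** summarize with the mean by default (`min` and
  `percentile90` available). Genes absent from the matrix contribute a
  neutral `missing_default = 0.5`, chosen to leave unmeasured genes
  uninformative while keeping measured zeros decisive — the distinction
  between "not expressed" and "not measured" is exactly what dropout
  imputation protects.

Acyclic circuits are evaluated exactly in topological order. Cyclic
circuits are iterated synchronously from $S = 0$ until the largest
absolute change falls below `tol = 1e-6` (at most `max_iter = 100`
sweeps); non-convergence is an error carrying the last residual, never a
silent result. Because all factors lie in $[0,1]$ the iteration is
monotone-bounded in practice; the suite checks fixed-point and topological
evaluation agree on random DAGs.

## Preprocessing

The activity model needs all genes on a common $[0,1]$ scale:
$\log(1+x)$, truncation at the per-gene 0.99 quantile (type-7, linearly
interpolated — fixed for reproducibility), then per-gene min–max scaling.
Per-gene scaling is the default because the propagation model reads each
gene relative to its own dynamic range; a matrix-global mode exists
(`per_gene = FALSE`) since the upstream convention is not fully
determined. Constant genes map to zero.

Dropout imputation (`impute_dropouts()`) follows the consensus-cluster
recipe: cells are clustered for every $k \in \{2,\dots,8\}$ under two
distances (Euclidean on log counts, Spearman correlation), with Ward
linkage, and each zero is replaced by the average over clusterings of the
within-cluster mean of its gene (cluster means include observed zeros, so
an all-zero gene stays zero). Nonzero entries are never touched. The
$k$-grid × distance consensus is this package's concrete choice within
that family of imputers.

Cell clustering for evaluation (`cluster_cells()`) runs k-means on a
two-dimensional embedding. The default embedding is the first two
principal components because it is deterministic; any externally computed
cells × 2 embedding (e.g. t-SNE) is accepted as a drop-in, since embedding
internals are outside this package's scope. Clustering agreement is
measured by the Rand index (pair-counting) with the adjusted version
reported alongside.

# Differential activity

Two cell groups are compared per circuit with a moderated t: pooled
variances are shrunk toward a prior fitted across circuits by
method-of-moments on log variances (no intensity trend — a deliberate
simplification of the full published shrinkage machinery, documented as
such and cross-checked in the test suite against the reference
implementation where available). When the observed variances show no
excess dispersion the prior degrees of freedom are infinite and every
variance shrinks completely to the mean variance. With $d_0 = 0$ the
statistic reduces exactly to the classical pooled two-sample t, which the
suite verifies on $10^4$ random instances. Constant circuits are guarded
by a variance floor of $10^{-12}$; circuits constant and equal in both
groups get $p = 1$. Benjamini–Hochberg adjustment controls FDR; the
default $\alpha$ is 0.05, two-sided. Only two-group contrasts are
supported — covariates and blocking are out of scope.

# Hallmark aggregation

Circuits inherit hallmarks from their **effector node's genes only** (the
effector is what triggers the cell function; linking via arbitrary member
genes would blur that reading). Annotations arrive as GMT. The summary
reports, per group, counts of significant circuits per hallmark and both
percentage views — share of the group's significant annotated circuits,
and share of all circuits annotated to that hallmark — plus a
common-versus-specific partition across groups. "Specific" is interpreted
as *significant in the group minus common to all groups* (not
exclusive-to-group); the alternative reading is possible and the choice is
recorded in the output metadata. A circuit annotated to $k$ hallmarks
contributes to $k$ cells of the table, so hallmark counts sum to at least
the number of significant annotated circuits.

# Drug perturbation

A drug is a set of (gene, action) pairs. Inhibitors and antagonists set
their target's normalized expression to 0, agonists to 1 (both
configurable; a fractional mode multiplies by $1-\text{efficacy}$).
Activities are recomputed and each cell is scored by the mean
$|\log_2((A'+\epsilon)/(A+\epsilon))|$ over the circuits containing a
target gene; $\epsilon = 10^{-3}$ on the $[0,1]$ activity scale bounds the
magnitude near 10 for a total shutdown. Restricting the aggregate to
target circuits matches the question being asked — what changes in the
circuits this protein participates in — and `sum`/`max` modes exist. The
responder/low-responder split uses 1-D 2-means rather than a fixed cutoff
because no principled threshold exists a priori; the midpoint of the
component means is reported as the operational threshold and a mean
silhouette width below 0.5 flags a weak split. The magnitude-of-change
score is this package's concrete interpretation of an informally described
quantity.

Two mechanisms produce low responders, and both are reproduced by the
synthetic study: cells whose target gene is already silent (nothing to
lose), and cells whose target shares its node with a highly expressed
compensator ligand, which keeps the node value — and hence the circuit —
alive after knockdown.

# The synthetic study

`simulate_study()` generates the full study the test and acceptance suites
run on: random signed DAG pathways (≥1 source, ≥1 sink, every retained
pathway yields ≥1 circuit; the first pathway's source node carries both
the drug target and its compensator), clustered negative-binomial counts,
and complete ground truth (cell types, planted circuits, resistant mask,
pre-dropout matrix and dropout mask — so imputation accuracy is directly
scorable).

Default study conditions, chosen once as a realistic plate-based regime:

| parameter | default | role |
|---|---|---|
| pathways × nodes | 6 × 10 | ~25–40 circuits |
| cell types × cells | 3 × 60 | three clusters |
| baseline mean, dispersion | lognormal(log 4, 1), NB size 3 | count noise |
| marker genes | 10% of 300 background genes, ×2^1.5 | cluster signal |
| planted circuits | 4 per non-reference type, genes ×2^2.5 | differential signal |
| dropout | $p=\exp(-0.12\,\log(1+\mu)^2)$ | ~65–70% zeros |
| resistant fraction | 15% of the last type, target ×0.05, compensator ×5 | resistance mechanism |

Dropout decays with expression (double-exponential form), matching the
empirical single-cell literature; the decay rate was set so the observed
zero fraction lands in the 60–80% band typical of plate-based data, and
$\lambda = 0$ is explicitly defined as "no dropout" (the formula's
degenerate limit would otherwise drop everything). Planted differential
signal is injected on *gene means*, never on activities, so the
propagation model is genuinely exercised end to end. Cluster separation
was fixed so that the planted types are recoverable from circuit
activities after imputation while raw dropout-ridden counts cluster
noticeably worse — the regime in which an imputation step earns its place.

Two analysis-design points that the synthetic study surfaced, worth
knowing when applying the package to real data:

* **Imputation benefit is assessed on activity clustering.** The model's
  motivation for imputing is that a dropout zero acts as a switch inside a
  circuit. Correspondingly, the end-to-end evaluation clusters the circuit
  activity matrix (as the original workflow does), where imputation is
  decisive; on the raw gene matrix a PCA/k-means clustering is much less
  sensitive to dropout and imputation may not help at all.
* **The perturbation analysis runs on observed (non-imputed) counts.**
  A cluster-mean imputer overwrites the near-zero target-gene values of a
  small resistant subpopulation with its cluster's mean, erasing the very
  phenotype of interest (this is visible in the generator: imputing before
  the drug simulation destroys low-responder recall). This is a general
  hazard of zero-replacing imputers for minority phenotypes, not an
  artifact of the generator.

What the generator does **not** emulate: UMI/read-level noise, ambient
RNA, batch effects, doublets, or realistic pathway topologies with shared
genes across pathways. Passing tests therefore demonstrate correctness of
the algorithms and recoverability under a fair synthetic regime, not
performance on any particular real dataset.

# Numerical and degenerate-input policy

* Activities, node values and perturbation overrides are validated into
  $[0,1]$; violations are errors, not clamps.
* Fixed-point iteration: `tol = 1e-6`, `max_iter = 100`, start at 0;
  non-convergence is an error.
* Quantiles are type-7 throughout.
* k-means runs are seeded explicitly (`nstart = 10`); identical seeds give
  identical labels, and the generator is bit-reproducible under its seed.
* Degenerate cases: all-identical impact scores → one all-responder group
  with a warning; all-zero variances → error; empty activation sets →
  factor 1; unreachable effectors → warning and no circuit; absent drug
  targets → warning, skip, and a record in the result.

# Problem sizes used by the checks

The acceptance checks run at the sizes that make their statistics
meaningful rather than maximal: 200 random circuits for the propagation
oracle, $10^4$ monotonicity perturbations, 100 partition pairs for the
Rand oracle, $10^4$ instances for the pooled-t equivalence, a
500-replicate null for type-I calibration, 2000 variances for prior
recovery, 10 seeds × (20 planted + 200 null circuits, 100 cells/group) for
sensitivity/FDR, 20 generator seeds for the imputation-clustering
comparison, and 10 seeds (90 planted resistant cells) for low-responder
recall. These were chosen as the package's own validation design.

# Known limitations

* Two-group contrasts only; no covariates, blocking or random effects.
* The EB prior fit omits the mean-variance trend of the full published
  method.
* Hallmark linkage is effector-only by design.
* The responder split assumes the impact distribution is usefully
  bimodal; the silhouette diagnostic flags when it is not, but the labels
  are still produced.
* Circuit extraction on cyclic graphs uses reachability semantics; exotic
  cyclic topologies may include nodes no simple path visits.
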