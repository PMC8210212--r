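# sccircuits

Mechanistic signaling-circuit activity analysis for single-cell
transcriptomics.

Single-cell RNA-seq measures what genes a cell transcribes, not what the
cell is functionally doing. `sccircuits` bridges that gap with a mechanistic
model of signal transduction: signed, directed pathway graphs are decomposed
into **circuits** — the sub-network connecting every possible receptor
(source) node to one effector (sink) node — and each cell's normalized
expression profile is propagated through each circuit to estimate how much
signal reaches the effector. On top of the per-cell circuit activities the
package layers the analyses a functional single-cell study needs:
differential circuit activity between cell groups, cancer-hallmark
summaries of the significant circuits, and per-cell simulation of targeted
drugs that separates responder from low-responder cells and exposes the
compensation mechanisms behind innate resistance.

It is aimed at computational biologists studying tumor heterogeneity,
drug response, or any setting where cell populations should be compared by
what their signaling circuits are doing rather than by marker genes alone.

## The model

A node *n* of a circuit carries one or more genes; its normalized
expression *v<sub>n</sub>* ∈ [0,1] summarizes those genes (mean by
default). The signal reaching node *n* is computed recursively along the
circuit's edges:

$$S_n = v_n \cdot \Big(1 - \prod_{s_a \in A}(1 - s_a)\Big) \cdot \prod_{s_i \in I}(1 - s_i)$$

where *A* and *I* are the signals arriving on activation and inhibition
edges. Receptor nodes receive one implicit activation of 1, so
*S*<sub>receptor</sub> = *v*<sub>receptor</sub>. The circuit's activity in
a cell is the effector's *S<sub>n</sub>*. Acyclic circuits are evaluated
exactly in topological order; cyclic circuits are iterated to a fixed
point. A node's expression therefore acts as a switch: a gene observed at
zero shuts its node down, which is why dropout imputation
(`impute_dropouts()`, a consensus-cluster averaging imputer) matters before
activity inference.

Differential activity uses an empirical-Bayes **moderated t**: per-circuit
variances are shrunk toward a method-of-moments prior
(s̃² = (d₀s₀² + d_g s_g²)/(d₀ + d_g)) and p-values are
Benjamini–Hochberg adjusted. Drug action is simulated per cell by setting
inhibited targets to a low value (agonized targets to a high value),
re-propagating, and scoring each cell by the mean |log₂ fold change| of the
circuits the target participates in; a two-means split labels responders
and low-responders.

## Worked example

The package ships a fully ground-truthed synthetic study generator, so the
whole pipeline runs without downloads:

```r
library(sccircuits)

sim <- simulate_study(seed = 1)
#> <sc_simulation> 416 genes x 180 cells; 3 cell types, 25 circuits,
#>                 9 resistant cells; 67% zeros

norm <- normalize_expression(impute_dropouts(sim$counts, seed = 1))
acts <- circuit_activities(norm, sim$truth$circuits)
#> <circuit_activity> 25 circuits x 180 cells; range [0, 1]

clusters <- cluster_cells(acts, k = 3, seed = 1)
truth <- setNames(as.integer(factor(sim$truth$cell_types)),
                  names(sim$truth$cell_types))
rand_index(clusters, truth)
#> # A tibble: 1 x 2
#>   rand_index adjusted_rand
#> 1      0.985         0.967
```

Clustering the *circuit activities* recovers the three planted cell types
almost perfectly (adjusted Rand 0.967) — after imputation; on the raw
dropout-ridden counts the same clustering is far worse, which is the point
of imputing first. Differential testing and hallmark aggregation:

```r
lab <- setNames(ifelse(sim$truth$cell_types == "type2", "type2", "other"),
                names(sim$truth$cell_types))
diff <- differential_circuits(acts, lab, group_order = c("type2", "other"))
#> <circuit_diff> 25 circuits; 16 significant at FDR < 0.05 (type2 vs other)
#>   prior: d0 = 3.292, s0^2 = 0.005898

ch <- annotate_circuits(sim$truth$circuits, sim$truth$hallmarks)
tidy(hallmark_summary(list(type2 = diff), ch))   # counts + both % views
```

The 16 circuits whose activity separates `type2` from the rest include the
planted ones, and the summary tabulates them per cancer hallmark. Drug
simulation (here an inhibitor of the generator's target gene, whose
receptor node also carries a compensator ligand):

```r
drug_res <- simulate_drug(normalize_expression(sim$counts),
                          sim$truth$drugs, sim$truth$circuits, seed = 1)
table(resistant = names(truth) %in% sim$truth$resistant_cells,
      label = tidy(drug_res)$label)
#>          label
#> resistant low_responder responder
#>     FALSE           155        16
#>     TRUE              9         0
```

All nine planted resistant cells (low target expression compensated by a
high co-node ligand) land in the low-responder class. `autoplot()` methods
exist for activity matrices, differential results, hallmark summaries and
perturbation results; `run_pipeline()` orchestrates every stage from files
and writes a provenance manifest.

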