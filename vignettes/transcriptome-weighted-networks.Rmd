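---
title: "Transcriptome-weighted metabolic networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptome-weighted metabolic networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(rasnet)
```

## The problem

Several biosynthetic pathways -- ganglioside biosynthesis is the motivating
case -- consist of parallel reaction series elongated by the *same*
promiscuous enzymes. The enzyme encoded by *B3GALT4*, for instance, extends
the 0-, a-, b- and c-series gangliosides alike. Any activity score derived
purely from the expression of the catalyzing genes therefore assigns
*identical* values to the corresponding steps of all series: transcriptome
data alone cannot say which series is actually running. `rasnet` addresses
this by combining per-reaction activity scores with the topology of the
metabolic network, so that the flow entering each series modulates the
scores of its downstream steps.

## The model

**Graph.** The pathway is a directed, metabolite-centric graph: nodes are
metabolites, each edge is a reaction converting the source into the target,
annotated with a gene--protein--reaction (GPR) rule. At most one edge per
ordered node pair is kept, so per-sample edge weights form a single
adjacency matrix $W$; if several reactions share a node pair their GPRs are
merged with OR semantics. Reversible reactions contribute both directions.
Degradation reactions that are not competing biosynthetic steps should be
removed before analysis (`remove_reactions()`), since they otherwise appear
as spurious outgoing flow.

**Reaction activity scores (RAS).** For each sample $s$ and reaction $r$,
the GPR rule is evaluated over the sample's normalized expression: genes
joined by AND encode subunits of one complex, so the minimum expression
limits the reaction; genes joined by OR encode isoforms, so their
expression values add. Evaluation is recursive for nested rules. Counts
are first normalized with the median-of-ratios size-factor estimator and
transformed as $\log_{10}(x + 1)$, so all activities are non-negative and
roughly variance-stabilized.

**Transition probabilities.** For one sample, the weighted adjacency $W$
is row-normalized into a transition matrix $T$: $t_{ij}$ is the
probability that a one-step random walker at metabolite $i$ proceeds to
$j$, with flow proportional to reaction activity. Rows with zero outgoing
activity are set to zero rather than uniform -- zero expression means zero
activity, and inventing flow there would propagate mass through silent
reactions. Three adjusted matrices are derived:

* $W_1 = W \circ T$: each activity is damped by its own branching
  probability. Only edges leaving a branch point change.
* $W_2 = W \circ T^a$ (recursive): every $t_{ij} = 1$ (a node's sole
  outgoing edge) is replaced by the largest plain TP among the incoming
  edges of $i$, recursing upstream until a value $\ne 1$ is found; a node
  with no incoming edges keeps 1. This pushes the branch decision down
  entire chains, so all steps of a series inherit the series' entry
  probability.
* $W_3 = W \circ T^b$ (path products): from a chosen source metabolite
  $x$, every simple path carries the product of its plain TPs (the product
  rule along a branch of a tree diagram); an edge's new value combines the
  products of all simple paths ending with that edge. Edges unreachable
  from $x$ get 0. For the glycosphingolipid graph the natural $x$ is
  lactosylceramide (`C01290`), where the pathway splits into the
  lacto-/neolacto-, globo- and ganglio-series.

Because every plain TP lies in $[0, 1]$, schemes $W_1$ and $W_2$ never
increase an activity, and on a branchless chain all three schemes are the
identity. These invariants are enforced by the test suite.

## Numerical choices and edge cases

* **Equality with 1** in the recursive scheme is tested with an absolute
  tolerance of $10^{-12}$; plain TPs of sole edges are exactly 1 by
  construction, so this only guards floating-point division.
* **Ties among incoming edges** with equal maximal TP are broken by the
  lexicographically smallest source node id, making results reproducible.
* **Recursive lookups use the original plain matrix**, never progressively
  updated values; both conventions agree on chains, and this one is
  independent of edge processing order.
* **All-1 cycles** in the recursive scheme resolve to 1 (a visited-node set
  guards the recursion).
* **Shared terminal edges** in the path scheme: the products of several
  simple paths ending on the same edge are summed by default, which on a
  DAG equals the probability that a random walk from $x$ traverses that
  edge; `combine = "max"` keeps only the best path instead. On cyclic
  graphs summed values can exceed 1; they are reported as-is with a
  warning.
* **Path explosion**: simple-path enumeration is capped (`max_paths`,
  default $10^5$) with a hard error, since dense graphs have exponentially
  many simple paths. The enumeration depends only on the graph structure
  and is shared across samples.
* **Missing genes**: a GPR gene absent from the expression matrix
  contributes 0 (with a warning), so an AND complex with an unmeasured
  subunit scores 0; a strict error policy is available. This is the
  conservative choice when datasets use different annotation versions.
* **Zero group means** in the differential log2 fold-change are guarded by
  a pseudocount $\varepsilon$ (default $10^{-9}$, recorded in the output
  attributes).

## Downstream analyses

**Differential reaction activity.** For two sample groups, each reaction's
activity distributions are compared with a two-sided two-sample
Kolmogorov--Smirnov test, alongside the log2 fold-change of group means.
The exact null distribution is used when both groups have at most 100
samples and the values are tie-free; ties degrade to the asymptotic
approximation with a warning. p-values are Benjamini--Hochberg adjusted
across *all* reactions in the matrix (not only a focal subgraph), and
pathway-level activity is the per-sample sum over member reactions, with
multi-pathway reactions contributing to each of their pathways.

**Unsupervised exploration.** Samples are embedded in 2-D with UMAP and
clustered on the embedding coordinates with HDBSCAN. Since no HDBSCAN
implementation ships with this package's dependencies, `hdbscan_labels()`
is a self-contained implementation of HDBSCAN*: core distances at
`min_pts`, mutual reachability distances, single-linkage hierarchy,
condensation at minimum cluster size `min_pts`, and excess-of-mass cluster
selection; outliers form the pseudo-cluster 0. Before embedding a
path-adjusted matrix, `scale_reactions()` removes all-zero rows (reactions
outside any path) and standardizes each remaining reaction, because path
products shrink with path length and would otherwise dominate the
embedding through scale alone.

UMAP is stochastic, so clustering one layout invites cherry-picking.
`stability_iterations()` repeats embedding + clustering with seeds
`base_seed + i` and records, per iteration, each sample's coordinate sum
$x + y$ (a 1-D summary that makes cluster membership traceable across
iterations in a line plot) and three internal validity indices computed on
the embedding coordinates with noise points excluded: the C-index
$(S_w - S_{\min}) / (S_{\max} - S_{\min})$, the Calinski--Harabasz index,
and the mean silhouette width. Indices are computed on the 2-D coordinates
rather than the high-dimensional matrix because they diagnose the
clustering actually performed, which operates on the embedding; when fewer
than two non-noise clusters exist they are reported as undefined rather
than extrapolated. Marker reactions per cluster come from Welch t-tests,
either against all other samples pooled (`vs_rest`, the default) or as the
maximum p-value over all pairwise cluster comparisons (`pairwise_max`),
which only calls markers separating a cluster from *every* other cluster;
with two clusters the modes coincide.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_neighbors` | 15 | UMAP locality; 3 suits cohorts of ~20 samples, 12--20 suits hundreds |
| `min_dist` | 0.1 | UMAP minimum embedding distance |
| `min_pts` | 5 | HDBSCAN minimum cluster size; scan it and prefer few outliers with moderate cluster sizes |
| `x` | `"C01290"` | source metabolite of the path scheme; choose the branch point of interest |
| `epsilon` | 1e-9 | fold-change pseudocount |
| `alpha` | 0.05 | BH-adjusted significance level |
| `max_paths` | 1e5 | simple-path enumeration cap |

The defaults for small cohorts (`n_neighbors = 3`, `min_pts = 5`) and
larger cohorts (`n_neighbors` 12--20, `min_pts = 10`) follow the
parameterizations that proved readable on neuroblastic-tumor cohorts of
21 and 154 samples respectively; all are configurable everywhere.

## What the synthetic generator does and does not emulate

`toy_graph_fig3()` reproduces the essential topology: a branch node
feeding two parallel chains whose corresponding steps share one gene, so
unadjusted activities are provably identical across chains while the
recursive and path schemes separate them whenever the branch activities
differ. `random_dag()` provides acyclic substrates for brute-force
validation of the path scheme. `simulate_counts()` draws grouped
negative-binomial counts (default dispersion 0.1, a typical bulk RNA-seq
value; default mean 100) with multiplicative group effects on named genes
and optional unaffected background genes that stabilize size-factor
estimation, emulating the rest of the transcriptome.

The generator deliberately does **not** emulate: realistic human
expression correlation structure, library-size gradients confounded with
group, isoform-level effects, or the actual glycosphingolipid gene
panel. Passing tests therefore demonstrate correctness of the algorithms
and calibration of the statistics under the stated count model -- not that
any particular biological conclusion transfers to real cohorts.

## Problem sizes used in the checks

The package's own verification uses: 200 random DAGs of up to 12 nodes for
the path-scheme oracle (tolerance $10^{-12}$); exact KS enumeration up to
5 samples per group; 1000 null simulations at $n = 20$ per group for
calibration of the raw $p \le 0.05$ rate; 100 simulations of a 2-fold
single-enzyme effect at $n = 30$ per group for power; and 100 seeded
embedding iterations on two well-separated 50-sample groups for cluster
stability. These sizes give stable Monte-Carlo estimates while keeping a
full verification run in the minutes range.

## Known limitations

* The path scheme depends strongly on the chosen source node; on graphs
  without a natural branch point it is not meaningful (whole-network use
  would need one source per pathway).
* Steady-state constraint-based modelling is intentionally out of scope;
  scores reflect transcriptional potential, not flux.
* KS ties (possible after aggressive rounding) reduce to the asymptotic
  approximation.
* HDBSCAN on very small cohorts (fewer than `min_pts` samples per genuine
  cluster) labels everything noise; the `min_pts` scan helper behavior is
  monotone, so lowering it is safe to explore.

## A compact end-to-end example

```{r example}
graph <- toy_graph_fig3()
sim <- simulate_counts(graph, fixture_spec(
  n_per_group = 10, seed = 1, n_background = 20,
  effects = data.frame(gene = "g_branch_a", log2_effect = 1, group = "A")
))
expr <- normalize_counts(sim$counts)
ras <- compute_ras(graph, expr)
w3 <- adjust_ras(ras, graph, scheme = "W3", x = "s")
diff <- differential_reactions(w3, sim$annotations)
glance(diff)
head(dplyr::arrange(tibble::as_tibble(diff), pvalue), 3)
```

The unadjusted rows of corresponding chain edges are identical
(`ras["R_ac", ] == ras["R_bd", ]`), while the path-adjusted rows are not --
which is the entire point.
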