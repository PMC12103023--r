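---
title: "Role-based embedding of signed gene regulatory networks"
author: "signedRoles maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Role-based embedding of signed gene regulatory networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signedRoles)
```

## The problem

A gene regulatory network (GRN) describes activating (`+`) and inhibiting
(`-`) relationships between genes. Comparing GRNs inferred from different
cell types or states is hard with proximity-based embeddings (node2vec,
DeepWalk and relatives), because two genes can only be embedded nearby when
they are connected — genes from two *separate* networks can never be
compared. Role-based (structural) embeddings invert the principle: two genes
are close when their *connection patterns* look alike, whether or not they
share any neighbour, and even when they live in different networks. This
package implements a role-based embedding for **signed** networks and two
comparative analyses built on it:

* **Differentially topological genes (DTGs)** — genes whose regulatory role
  changes between cell types or states, a complementary axis to
  differential expression;
* **Gene-module stability** — how much a module of co-clustered genes
  collectively shifts between two states.

## The model

**Signed degree.** Each gene is summarised by the 2-vector
$d = [d^+, d^-]$ counting its positive and negative edges. This is the
elementary descriptor: a hub of activators, a hub of repressors, and a leaf
on a single inhibitory edge are all distinguishable already at this level.

**Local cost (EBED).** GRN degrees are roughly power-law distributed, so
raw Euclidean distances between degree vectors are dominated by hubs. The
exponential biased Euclidean distance first takes the log of the (+1
shifted) degree ratios per sign component, measures the Euclidean norm of
the two log-ratios, and exponentiates back:

$$\mathrm{EBED}(d_u, d_v) \;=\; \exp\sqrt{
  \ln^2\frac{d_u^+ + 1}{d_v^+ + 1} + \ln^2\frac{d_u^- + 1}{d_v^- + 1}}.$$

With the natural logarithm (chosen so that the outer exponential exactly
counterbalances it) the distance is symmetric, always at least 1, equals 1
exactly for identical degrees, and reduces to
$\max(a{+}1, b{+}1)/\min(a{+}1, b{+}1)$ when only one sign component is
populated. As printed the formula has an ambiguous parenthesis; we read the
exponential as wrapping the whole square root, and expose an
`ebedMinusOne` switch (identical degrees score 0) as a sensitivity variant.

**Multi-hop comparison.** Let $R_k(u)$ be the *degree ring*: the sorted
sequence of signed degrees of all genes exactly $k$ hops from $u$ (hops on
the unsigned union of both edge sets — sign affects cost, not
reachability). Rings of two genes differ in length, so they are aligned
with dynamic time warping (steps $(1,0), (0,1), (1,1)$, sum aggregation,
EBED as local cost) and accumulated:

$$f_0(u,v) = \mathrm{EBED}(d_u, d_v), \qquad
  f_k(u,v) = f_{k-1}(u,v) + \mathrm{DTW}(R_k(u), R_k(v)).$$

Rings are sorted ascending by (total degree, $d^+$, $d^-$); the
total-degree-major order matches the scale-free motivation and gives DTW a
meaningful monotone alignment. When either ring is empty at some $k$ the
pair stops accumulating (DTW is undefined on empty input); deeper layers
simply carry no link for that pair.

**Multilayer graph and walks.** Layer $k$ connects every comparable pair
with weight $w_k = e^{-f_k}$. Each gene is linked to its own copy one layer
up with weight $\ln(\Gamma_k(u) + e)$, where $\Gamma_k(u)$ counts the
gene's layer-$k$ links whose weight strictly exceeds the layer's mean link
weight, and one layer down with weight 1. Since $\ln(\cdot + e) \ge 1$, the
walk is biased upward, toward layers that integrate wider neighbourhoods.
Biased random walks start at layer 0; an intra-layer step (probability
$q = 0.8$, split across links by weight) emits the destination gene as a
token, an inter-layer step (probability $1 - q$, split between up and down
by their weights; at the boundary layers all of it goes to the one
available direction) changes layer silently. Inter-layer moves append
nothing so that the Skip-Gram vocabulary consists of genes only.

**Embedding.** Skip-Gram with negative sampling over the walk corpus
(window 5, 5 negatives, 5 epochs, learning rate 0.025 decaying linearly).
The implementation is single-threaded and consumes only R's RNG, so a seed
fixes the output bit-for-bit. No R implementation of Skip-Gram was
available to build on, so the trainer is part of the package (C++).

**Joint spaces.** Networks from several contexts are merged as a disjoint
union with node identifiers `gene::context` (the separator is reserved).
No edge crosses contexts, yet $f_k$ is computed across the full merged node
set — that is precisely what places genes from different networks near one
another when their roles match, and it is validated by the isomorphic-copy
and automorphic-twin tests.

## Downstream statistics

For a gene $u$ present in all $C$ contexts, with embeddings
$\mathrm{emb}_u^c$: the centroid $\mathrm{cen}_u$ is their mean, the
per-context distance is $d_u^c = \lVert \mathrm{emb}_u^c -
\mathrm{cen}_u\rVert_2$, $\bar d_u$ is the mean of the $d_u^c$, and
$\sigma_u$ their **population** standard deviation (divide by $C$).

* $C = 2$: the genes in the top 10% of $\bar d_u$ (rank-based,
  $\lceil 0.1N \rceil$, deterministic under ties) are flagged DTGs. For two
  contexts both $d_u^c$ equal half the pair distance, so centroid and
  pair-distance rankings coincide.
* $C > 2$: the top 5% of $\bar d_u$ are flagged (consistent role change in
  every context), plus genes with $\sigma_u$ above a threshold (role change
  confined to particular contexts). The threshold defaults to 0.4 — an
  empirical value appropriate for embeddings on the scale produced by the
  default training settings — and can be replaced by the 95th percentile of
  the observed $\sigma$ (`sdAuto = TRUE`), which adapts to the embedding
  scale.
* Genes absent from any context are excluded and listed separately; a gene
  must keep at least one connection in every network to be comparable, a
  stated limitation of the approach.

**Module stability.** Louvain communities are found on the anchor context's
unsigned union graph with unit weights (modularity is undefined for
negative weights; signs are kept everywhere else). Modules with fewer than
10 genes are excluded from the report. Per module: the mean of
$\lVert\mathrm{emb}_u^{c_1} - \mathrm{emb}_u^{c_2}\rVert_2$ over genes
shared with the comparison context, and NA%, the fraction of module genes
absent from that context.

**Topology metrics.** Eight per-gene descriptors: degree centralities
$d^\pm/(n-1)$; normalised betweenness and eigenvector centrality on the
unsigned union (configurable to either sign-restricted subgraph); local
clustering per sign (0 when a gene has fewer than two same-sign edges);
and each sign-subgraph's degree assortativity attributed to its members.
`clusterProfile()` clusters the embedding with seeded K-means (default
$K = 10$, 10 restarts) and reports per-cluster metric means with a
per-metric min–max scaled matrix for heatmaps.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `kMax` | 3 | deepest hop compared; capped at the deepest layer where two non-empty rings remain. Three hops covers the 1- and 2-hop neighbourhoods that motivate multi-hop comparison, plus one. |
| `q` | 0.8 | intra-layer transition probability |
| `walksPerNode` / `walkLength` | 10 / 80 | corpus size per gene (tokens) |
| `dim` | 128 | embedding dimension (2 for visualisation; tests use 16–32) |
| `window`, `negative`, `epochs` | 5, 5, 5 | Skip-Gram settings, common node-embedding practice |
| `rhoThreshold`, `pThreshold` | 0.3, 0.01 | Spearman GRN edge filters (raw p; `fdr = TRUE` for BH) |
| `sdThreshold` | 0.4 | multi-context SD rule (or `sdAuto`) |
| `maxNodes` | 3000 | guard on the quadratic all-pairs stage |

## Synthetic data: what it emulates and what it does not

The generators are first-class, seeded, pure functions of their parameters:

* `makeSimTree()` — a fixed 31-gene signed tree with a root hub, five
  intermediate hubs with leaf fans, and two leaves attached by single
  negative edges (S9, S15). Those two are automorphic twins: the canonical
  probe that a role-based method must place together although they are four
  hops apart. The exact topology is this package's own construction
  realising that role structure; it is also shipped as a plain edge list.
* `makeScaleFree()` — preferential attachment (degree + 1 weighting from an
  edgeless seed graph, giving exactly `mAttach * (n - mAttach)` edges) with
  i.i.d. negative signs, emulating the scale-free degree and configurable
  inhibition fraction of real GRNs.
* `makeTwinPairs()` — a scale-free core plus planted automorphic pairs
  attached to identical anchors with identical signs.
* `makePerturbedPair()` / `makeMultiContext()` — copies of a base network
  with selected genes structurally rewired. Rewiring swaps the far
  endpoints of same-sign edge pairs (degree-preserving, so bystanders keep
  their signed degree) and flips the sign of up to two incident edges in
  one direction — preferring edges between selected genes — so every
  selected gene's signed degree moves by at least 2 in L1 while edge count
  and degree sequence are preserved. The multi-context variant plants one
  class rewired in every context (high mean distance) and one rewired in a
  single context (high SD).

What passing these tests shows: the pipeline recovers *planted structural
ground truth* under realistic degree distributions and sign fractions. What
it does not show: performance on real inferred GRNs, whose edges carry
correlated noise from expression sampling and network inference — there is
no ground truth there, and nothing here models inference artefacts,
directionality, or edge-weight uncertainty.

## Numerical and design choices

* DTW is the exact $O(|s||t|)$ dynamic programme; the local cost is
  memoised over distinct signed-degree classes (pure caching, not sequence
  compression). A banded approximation was deliberately not implemented.
* The layer mean in $\Gamma$ is taken over *all* links of the layer
  (strict `>`), the literal reading; a per-node variant was considered and
  rejected as a second knob with no observable benefit.
* Degenerate inputs: constant genes are skipped in the Spearman GRN with a
  warning; a node without intra-layer links sends its full walk mass to the
  inter-layer moves; identical embeddings still flag 10% of genes in the
  paired DTG rule (the rule is rank-based by design — callers should check
  the distance column, and the report keeps it).
* Ties: edge selection in `topKEdges` orders by (|weight| desc, pair key);
  DTG flags by (distance desc, gene id); HVG by (variance desc, gene name).
  All reported tables are therefore deterministic.
* Reproducibility: walks and training consume R's RNG in fixed order on a
  single thread; identical inputs and seeds give byte-identical saved
  embeddings. Multi-worker training was deliberately left out.
* Problem sizes in the shipped tests (twin fixtures of 150 genes,
  isomorphic copies of 100, paired perturbation at 300 genes / 30 rewired,
  five seeds each) were chosen as the smallest scales at which the
  scale-free structure and the planted signals are comfortably expressed;
  all are parameters of the generators, not limits of the method.

## Known limitations

* The all-pairs $f_k$ stage is quadratic in merged node count; the default
  guard refuses runs above 3000 nodes rather than silently approximating.
* Only undirected networks are modelled: signed degree has no in/out
  split, so directed inputs are collapsed (reciprocal edges with equal
  sign merge; opposite signs are a conflict, by default an error).
* A gene isolated in one context cannot be compared across contexts; such
  genes are reported, not scored.
* The SD rule's absolute threshold depends on the embedding scale; prefer
  `sdAuto = TRUE` when comparing across training configurations.

## A worked run

```{r example, eval = FALSE}
base <- makeScaleFree(300, mAttach = 2, negFraction = 0.3, seed = 11)
pp <- makePerturbedPair(base, kGenes = 30, seed = 12)
emb <- embedNetworks(mergeNetworks(list(pp$netA, pp$netB)),
                     kMax = 3, dim = 32, seed = 101)
report <- classifyDTGs(emb)
head(report[, c("gene", "meanDist", "flag")])
mean(report$gene[report$flag == "dtg_mean"] %in% pp$perturbed)
```

The same pipeline is exercised end-to-end, with planted ground truth and
explicit pass criteria, in `tests/testthat/` and `scripts/acceptance.R`.
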