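---
title: "degnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{degnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degnet)
```

## The model

`degnet` formalizes a combinatory transcriptomic/network workflow. The
input is (a) one or two differential-expression contrasts (gene symbol,
log2 fold change, BH-adjusted q-value), (b) cellular-component gene-set
memberships with an optional parent→child hierarchy, (c) one
protein–protein interaction edge table per gene set in STRING's
`string_interactions.tsv` dialect, and (d) a map from gene sets to named
subcellular structures. The output is a per-structure account of how
strongly and in which direction the structure is regulated, and a ranked
shortlist of the genes that carry that regulation in topologically
important network positions.

The gene-level score at the core of the package is

$$W \;=\; BC \cdot CCe \cdot \log_2(NC) \cdot CCo^2 \;-\; \log_2(V \cdot AVP)$$

computed on the undirected, unweighted graph of each term's thresholded
interaction network. The multiplicative part rewards genes that relay many
shortest paths (betweenness $BC$), sit close to the rest of their
component (closeness $CCe$), have well-connected neighbors ($NC$) and a
cohesive neighborhood ($CCo$, squared, so neighborhood cohesion is
deliberately emphasized); the subtracted $\log_2(V \cdot AVP)$ penalizes
membership in large, sparse components where centrality is cheap.

The formula as written in running text is ambiguous in two places
("CCo2", "log2 V×AVP"). The package adopts the minimal reading consistent
with the token order — $CCo^2$ as a square and one penalty term
$\log_2(V\cdot AVP)$ — and isolates the evaluation in a single function
(`compute_weights()`), so an alternative grouping is a one-line change.
The parse is recorded in every run manifest.

### Zero substitution

$W$ is a product, so a single zero factor would erase all other evidence
about a gene. Before evaluation, any $BC$, $CCe$ or $CCo$ equal to 0 is
replaced by the *smallest non-zero value of that metric in the same
network*; when a metric is zero for every node of a network, the value
$10^{-7}$ — below any non-zero value these metrics produce on networks of
the size the pipeline handles — is used instead. $NC$, $AVP$ and $V$ are
never substituted. The rule is applied per metric, per network, and is
idempotent.

### Metric conventions

* **Betweenness** is unnormalized (raw shortest-path pair counts), the
  default of the common graph toolkits; a normalized variant would rescale
  all weights of a network by the same positive constant and leave
  within-network rankings unchanged.
* **Closeness** is normalized within the connected component,
  $CCe = (V-1)/\sum_j d_{ij}$, so it is bounded in $(0, 1]$ and comparable
  across networks of different sizes. The unnormalized convention
  $1/\sum d$ differs by the positive factor $(V-1)$ only.
* **$V$** is the size of the node's connected component, matching a
  per-node reading of "number of vertices"; distance-based quantities
  ($BC$, $CCe$, $AVP$) are computed within components so every value is
  finite without infinite-distance conventions.
* Nodes with fewer than two neighbors have $CCo = 0$ (then substituted);
  nodes exist only through edges, so degree ≥ 1 and $NC ≥ 1$, which keeps
  $\log_2(NC) \ge 0$.
* Edges are unweighted: the combined score gates membership (default
  threshold 0.900, STRING's "highest confidence") and plays no further
  role.

## Enrichment and term selection

Overrepresentation uses the two-sided Fisher exact test on the 2×2 table
(in term / not, differential / not), with members first intersected with
the tested-gene universe, followed by Benjamini–Hochberg correction across
all tested terms. Direction is classified from the counts: *positive* only
when the observed overlap strictly exceeds the expected value
$n_{deg} \cdot n_{term} / n_{universe}$; an overlap exactly at expectation
is not over-represented and counts as negative. A one-sided
(`alternative = "greater"`) variant is available.

Term selection retains terms that are significant (FDR < 0.05), positive,
and no larger than 2000 genes (the practical node limit for building an
interaction network). The manual practice of following each significant
branch to its most specific node is formalized as the *deepest-child
rule*: a candidate term is dropped whenever one of its descendants is also
a candidate. Chained hierarchies are handled transitively, so a
grandparent is dropped even when the intermediate term itself fails the
filters. Every exclusion is logged with its reason (`fdr`, `direction`,
`size`, `has_retained_descendant`).

## Aggregation rules

* Within a structure category, a gene annotated to several term networks
  keeps its **maximum** weight; the winning term is kept as provenance,
  with ties going to the lexicographically first term id.
* Fold-change summaries (sums of $|log_2FC|$ and of the positive and
  negative parts) run over the *distinct* differential genes annotated to
  the category's terms. Weighted summaries (mean $W$, mean
  $log_2FC \cdot W$) run over the category's weight-bearing genes — a
  differential gene can be annotated to a term yet absent from its
  network, so both gene counts are reported side by side.
* "Combined" regulation is the signed product $log_2FC \cdot W$ averaged
  per category: the product is the only simple combination that both
  preserves the regulation sign and scales by topological importance. It
  is isolated in `structure_weighted_summary()` should a sum- or
  rank-based alternative be preferred.
* The top-fraction ranking takes the top $\lceil f \cdot n \rceil$ genes
  per category (default $f = 0.1$), sorted by weight descending with ties
  broken by larger $|log_2FC|$ and then by symbol, making every output
  invariant to input row order.
* Categories with no genes report explicit `NA` means and `n_genes = 0`
  rather than silent zeros.

## Input handling

DEG tables are filtered with a *strict* inequality q < 0.05 (a cut "below
the threshold" reads as strict; the threshold is configurable). Missing
adjusted p-values — which DESeq2 emits under independent filtering — are
treated as not significant and dropped. Gene identity is the upper-cased
symbol, since DE tables and STRING node names must join on a common key;
the package requires pre-matched symbols and surfaces unmatched genes
rather than attempting alias resolution. Self-loops in edge tables are
dropped with a warning, reversed duplicate pairs are merged (keeping the
highest score), and scores outside $[0,1]$ are format errors.

## The synthetic benchmark

The generator emulates the study conditions the pipeline is meant for: a
gene universe of a few thousand symbols with a minority of differential
genes, terms of tens-to-hundreds of genes with controlled DEG enrichment,
and one network per term with planted high-centrality genes.

* **DEG tables** draw q-values directly — uniform on $[0, 0.05)$ for true
  DEGs, uniform on $[0.05, 1]$ otherwise — rather than simulating a count
  model: the pipeline never touches counts, so DESeq2 internals would add
  nothing. Differential log2 fold changes are normal with sd
  `effect_sd` (default 1, a typical spread for a strong contrast);
  background genes get sd `effect_sd/4`.
* **Annotations** sample members without replacement with odds multiplier
  `enrichment_odds` for DEGs in enriched terms; `enrichment_odds = 1`
  yields exactly null terms, which is what the calibration test uses. A
  shallow hierarchy is built by redrawing every second term of the first
  half as a subset of its predecessor, so deepest-child selection is
  exercised on terms whose significance is correlated, as in a real
  ontology.
* **Networks** grow by preferential attachment with a fitness mass
  concentrated on the planted hubs (`hub_degree_factor * mean_degree`
  versus 1), which yields heavy-tailed degrees with the hubs on top. Pure
  preferential attachment, however, leaves a high-degree hub with
  vanishing clustering ($CCo \sim 1/\text{degree}$), and because $W$
  multiplies by $CCo^2$, such a hub would *not* rank as top-central under
  the package's own score — moderately clustered mid-degree nodes would.
  Planted hubs are therefore additionally given partially closed
  neighborhoods: each pair of a hub's neighbors is connected with
  probability 0.2. This mirrors the dense, complex-like neighborhoods of
  "party hubs" in real protein interaction networks and makes the planted
  ground truth genuinely top-central by construction. The closure
  probability is a generator default chosen once on those domain grounds,
  not a fitted quantity.
* Edge scores are uniform on $[0.900, 0.999]$: the pipeline thresholds
  edges and never weights them.

What passing the planted-truth tests shows is that the pipeline recovers
*constructed* importance under realistic graph shapes; it does not show
that the weight formula identifies biologically validated key genes —
that depends on the quality of the input networks and annotations.

## Verification strategy and problem sizes

Every numerical component is checked against an independent brute-force
oracle written without the production code paths: Floyd–Warshall
distances plus explicit (pruned) shortest-path enumeration for the graph
metrics, exhaustive fixed-margin 2×2 table enumeration for the Fisher
p-value, and a hand step-up implementation for BH. The test suite covers
every connected graph up to isomorphism on ≤ 6 nodes plus 200 random
7–8-node graphs (metric agreement to 1e-10), all 2×2 margins up to 25
(agreement to 1e-12), 400 null terms for calibration (FDR rejections
≤ 7%), and a 50-replicate planted-hub benchmark with four 200-node
networks per replicate (top-10% recovery ≥ 90%, hub/non-hub weight
separation in ≥ 95% of replicates). These sizes keep the full suite at
about two minutes on one CPU while leaving each property comfortably
over-determined.

## Known limitations

* Symbol-based joining: genes whose DE-table symbol differs from the
  STRING preferred name are silently absent from networks (they are still
  counted in annotation-based summaries). An identifier-mapping layer is
  out of scope.
* The weight formula mixes quantities on very different scales
  (unnormalized betweenness grows with network size; the other factors
  are bounded), so weights are comparable within a structure category but
  only loosely across datasets.
* The deepest-child rule uses only the supplied hierarchy; with no
  hierarchy every significant positive term of admissible size is
  retained.
* Two-contrast runs share one network scoring (topology does not depend
  on the contrast); only the gene lists and fold changes differ.
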