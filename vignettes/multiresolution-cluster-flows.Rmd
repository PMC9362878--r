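---
title: "Methods: multi-resolution cluster flows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-resolution cluster flows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellflows)
```

## The model

Graph-based clustering of single-cell expression profiles optimises a
modularity benefit function whose resolution parameter controls the
granularity of the partition. Rather than committing to one resolution,
`cellflows` represents an entire sweep as a layered directed acyclic
graph. Its two inputs are deliberately minimal and method-agnostic:

1. a cell-by-resolution matrix of integer cluster assignments (any
   clustering method may have produced it), and
2. the corresponding cell-by-gene normalised expression matrix.

Each resolution is a column of nodes — one node per cluster, sized by its
cell count. Within a column, labels are permuted so that label 0 is the
largest cluster (ties broken by original label, making the relabelling
idempotent). An edge, or *flow*, between adjacent columns is the set of
cells shared by a cluster at resolution $j$ and a cluster at the next grid
value $j+q$; its count is the corresponding entry of the source-by-target
contingency table, and zero-count pairs produce no edge. Because every
cell is assigned at every resolution, exact integer conservation holds:
node sizes per column sum to the total cell count, and an interior node's
incoming and outgoing flow counts each sum to its size. Flows connect
*consecutive* grid columns only; comparisons across larger gaps are out
of scope, and no proportion threshold is applied when building — the
structure is lossless, and filtering is a render-time option (the HTML
view has a slider for it).

## Co-expression (GEP) and painting

For an ordered geneset $E$ of $n = 3$ genes over a flow of $m$ cells the
gene expression percentage of gene $i$ is

$$\mathrm{GEP}_i \;=\;
\frac{\sum_{j=1}^{m} E_{i,j}}{\sum_{j=1}^{m}\sum_{k=1}^{n} E_{k,j}},$$

a ratio of summed expression, so it is invariant to cell order and to any
common positive rescaling of the geneset. The three fractions are
barycentric coordinates of a ternary chart (one point per flow, point
size $2\log_2 m$) and map linearly to RGB: channel $i$ is
$\mathrm{round}(255\cdot\mathrm{GEP}_i)$, rounding half away from zero,
with the geneset order fixing the channel assignment (first gene = red).
A flow in which none of the three genes is expressed has an undefined
triple; it is excluded from the ternary dataset and painted a neutral
grey (`#BEBEBE`). Single-gene painting uses the arithmetic mean of the
gene over the flow's cells, min–max normalised over all flows by default
(one global scale bar; a per-column option exists) and looked up in a
named colormap; if all flows share one value the midpoint colour is used.
Expression is taken as provided — the package never normalises or
log-transforms it, since upstream pipelines differ and either scale is a
valid painting choice.

## Cluster evaluation and markers

Per-cluster silhouette uses the standard per-cell contrast
$s(i) = (b_i - a_i)/\max(a_i, b_i)$ with Euclidean distances in the
user-supplied embedding (the same space in which neighbours are found);
$a_i$ excludes the cell itself, singleton clusters and degenerate
$a=b=0$ cells are scored 0, and the cluster value is the mean over
members, in $[-1, 1]$. Node painting uses the affine normalisation
$(s+1)/2$ — chosen over min–max because it is a fixed bijection of the
silhouette's natural range and therefore comparable across graphs; min–max
remains available for metrics without a bounded range. Calinski–Harabasz
and Davies–Bouldin are whole-partition indices computed from their
textbook definitions and attached to every node of the column.

Marker tags are one-vs-rest Wilcoxon rank-sum tests per gene (normal
approximation with tie correction, no continuity correction; a
zero-variance gene gets $p = 1$), ranked by ascending $p$ with ties broken
by descending mean difference, reported with Benjamini–Hochberg FDR. The
default of five tags per node matches the hover-text convention. These
tags are descriptive labels, not calibrated inference — pseudobulk or
model-based differential expression is deliberately out of scope.

External annotations (for example enrichment scores computed by an online
service) are ingested from a `(resolution, cluster)`-keyed table rather
than computed: enrichment itself is an external service's output, so the
package reproduces the node-annotation behaviour generically.

## Stable paths

The tracing rule had to be designed here: stability is defined as the
mutual proportion $\min(\mathrm{count}/|\mathrm{source}|,
\mathrm{count}/|\mathrm{target}|)$, which is symmetric, lies in $(0,1]$,
and is thresholdable by a single $\tau$ (default 0.9). For
$\tau > 0.5$ the pigeonhole principle guarantees at most one stable
in-edge and out-edge per node, so maximal chains are well defined and
node-disjoint; for smaller $\tau$ the implementation steps only through
flows that are simultaneously the unique stable out-edge of their source
and unique stable in-edge of their target, preserving both properties at
any threshold. A path's score is the minimum mutual proportion along it,
its core the intersection of all step member sets; raising $\tau$ can only
shorten paths. Note the boundary semantics: if a community's children
first appear as separate clusters at grid value $r$, the intact
community's path ends at the column *before* $r$ and each child's path
starts *at* $r$ — the split resolution is read off the children's first
column.

## Resolution scan

When only expression and an embedding exist, the scan builds the
assignment matrix: exact k-nearest neighbours by Euclidean distance in
the embedding (ties broken by cell index, so results are deterministic),
shared-nearest-neighbour weights as the Jaccard overlap
$|N_u \cap N_v| / |N_u \cup N_v|$ of the two k-neighbour sets (self
excluded), pruning of weights below 1/15, and Louvain modularity
optimisation (via igraph) once per grid resolution with the seed re-fixed
before each run. Defaults $k = 20$ and prune $= 1/15$ follow common
single-cell practice; they are conventions, not reproductions of any
particular analysis. Neighbour search is exact rather than approximate —
at the scale this tool addresses (thousands to tens of thousands of
cells) the $O(n^2)$ distance pass is cheap and removes a source of
irreproducibility. Cluster counts generally grow with resolution but the
optimiser makes no monotonicity guarantee per cell; only the tendency is
asserted on planted fixtures.

## The synthetic generator

`planted_hierarchy()` plants a tree of populations: every non-root node
owns a block of marker genes (default 2) whose mean is `boost` (default
5) in all cells beneath it and `baseline` (default 0.2) elsewhere, so
populations that split late are molecularly close; expression is the
prototype mean under multiplicative lognormal noise
($\mu \cdot e^{\mathcal N(0,\sigma^2)}$, $\sigma = 0.3$, clipped at 0),
and the embedding is the PCA of the generated matrix (10 components).
Ground-truth assignments cut the tree at each grid value, so finer
columns nest exactly inside coarser ones — which is what makes expected
flows exactly computable and every backward proportion 1 on ground truth.
The PBMC-like preset fixes 2700 cells, 8 leaves in a 3-level hierarchy
over the grid 0.1–0.5 (step 0.1), yielding 4, 5, 7, 8, 8 clusters, with
three designated co-expression markers high in three disjoint lineages so
GEP triples reach all ternary corners.

What the generator does *not* emulate: count-level noise (dropout,
library-size variation), batch effects, doublets, or continuous
trajectories. Passing tests therefore demonstrate correctness of the
graph construction, statistics and tracing on well-posed inputs — not
robustness of upstream clustering to real scRNA-seq noise, which is the
clustering method's concern, not this tool's.

## Numerical and design choices

* Node identifiers are `"<resolution>_<label>"` with the resolution kept
  as the *input header string*, never re-rendered from a float, so
  `0.30000000000000004`-style drift cannot occur.
* Layout is the classic layered barycenter heuristic (4 sweep rounds,
  flow-count-weighted, ties by label); a sweep is kept only if it does
  not increase the crossing count, so the result is never worse than the
  size-order layout. Optimal crossing minimisation is NP-hard and not
  attempted. Node heights are proportional to size with a 0.05 gap
  fraction per column.
* JSON export is compact, fixed key order, numbers at 15 significant
  digits; `NA` annotations and empty maps are omitted. These choices make
  export → import → export byte-identical.
* GEP denominators of exactly 0 are the only undefined case; sums are
  plain double accumulation, and the sum-to-one property holds to
  machine precision (asserted at $10^{-9}$).
* All randomised steps (generation, community detection) take explicit
  integer seeds; the same seed gives bit-identical output.

Problem sizes in the test-suite and acceptance runs — the 2700-cell
preset for end-to-end checks, 150–1000-cell fixtures against quadratic
brute-force oracles, fifty random matrices up to $10^4$ cells for
conservation — were chosen so a full run completes in well under a minute
per property while still exercising every code path at realistic scale.

## Known limitations

* Flows only link adjacent grid columns; a cluster that dissolves and
  reforms two columns later is not connected.
* Silhouette is quadratic in cells per column; very large datasets should
  be subsampled for metric annotation (the acceptance script demonstrates
  a systematic 1-in-6 subsample).
* The ternary view is fixed at three genes: the GEP ratio generalises to
  any $n$, but the chart does not.
* The stability rule is this package's reinterpretation of
  community tracing; other definitions (e.g. Jaccard-based) would give
  different path boundaries.
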