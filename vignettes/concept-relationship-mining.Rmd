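---
title: "Mining transitive concept relationships with hub-removal labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining transitive concept relationships with hub-removal labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conceptpaths)
library(tibble)
```

## The problem

Biomedical thesauri such as the UMLS Metathesaurus link millions of concepts
(drugs, diseases, genes, findings) by semantic relations. Treating each
concept as a vertex and each relation as an undirected edge yields a large,
sparse, power-law graph on which *transitive associations* — indirect
A–B–…–C chains in the spirit of Swanson's ABC model — are a standard engine
of hypothesis generation: two concepts that are connected by many short
paths through concrete intermediates are plausibly related even when no
direct edge records that fact.

Ad-hoc search (DFS/BFS per query) does not scale to graphs of this size, and
raw shortest-path distance is fragile: one spurious edge can collapse the
distance between unrelated concepts. `conceptpaths` addresses both problems
with (i) a precomputed hub-removal distance labeling that answers
distance and multi-path queries by comparing two per-vertex labels, and
(ii) a closeness measure aggregated over the whole collection of discovered
paths, weighted by how concrete the concepts on each path are.

## The index: k-neighborhood decentralization labeling (kDLS)

The index (`build_index()`) exploits the heavy-tailed degree distribution.
Vertices are processed in order of residual degree (`hub_removal_order()`;
ties broken by lexicographically smallest id). Each hub in turn runs a
breadth-first broadcast of depth at most `k` in the *current residual
graph*, with the hub still present, writing a record

> (hub, distance to hub, BFS-tree predecessor)

into the label of every vertex reached — including its own self-record at
distance 0 — and is then deleted from the residual graph. High-degree hubs
therefore stamp their exact local distances onto essentially the whole
graph before it fragments, and later broadcasts are cheap because the
residual graph shatters quickly.

Two labels answer queries without touching the graph:

* `query_distance(u, v)` returns the minimum of `d(u,w) + d(w,v)` over
  shared hubs `w`. Any shared-hub sum is the length of a real walk, so the
  answer never undershoots the true distance; and whenever the true
  distance is at most `k`, the *first vertex of a shortest path to be
  removed* broadcast exact sub-distances to both endpoints while the whole
  path was still intact, so the answer is exact.
* `query_paths(u, v)` rebuilds, for every shared hub, the two predecessor
  walks and concatenates them; non-simple concatenations are dropped and
  duplicate vertex sequences removed. Whenever the true distance is within
  `k`, at least one reconstructed path attains it.

The default `k = 6` keeps the guarantee region generous (six hops covers
the bulk of useful transitive chains on thesaurus graphs) while keeping
labels small. Each record stores a single predecessor, so one path is
reconstructed per (endpoint, hub, endpoint) triple and labels stay O(1) per
record; this trades path multiplicity for index size and is the reason
`query_paths()` returns "a collection of paths including the shortest
ones", not all simple paths. Broadcast expands neighbors in lexicographic
id order, making predecessors — and hence every downstream result —
deterministic. Isolated vertices still carry their self-record; they simply
never share a hub with anything.

`save_index()`/`load_index()` persist the labels as versioned,
gzip-compressed JSON lines (a header with `k`, the vertex count and the
removal order, then one line per label).

```{r}
g <- toy_graphs()$square # a - b - c - d - a
idx <- build_index(g, k = 6)
query_distance(idx, "b", "d")
tidy(query_paths(idx, g, "b", "d"))
```

## Semantic weighting and the closeness measure

Concept semantic types (e.g. "Disease or Syndrome") form a DAG from
abstract roots to concrete leaves. `semantic_type_network()` assigns each
type a *reverse topological level* `h` by iterative leaf removal: leaves
get level 1, then the new leaves get level 2, and so on — equivalently,
`h(t)` is one plus the longest child-ward path from `t` to a leaf. A
concept's weight is `g = 1/h` using, for multi-typed concepts, the type
closest to the leaves (minimum `h`, hence maximum weight). Abstract
concepts that connect to everything are thereby down-weighted.

The closeness between two concepts is

$$R(u,v) = \sum_{p \in P(u,v)} \prod_{x \in p} g(x),$$

where `P(u,v)` is the set of simple paths discovered by the index,
*excluding paths of length 1*: a lone direct edge is existing knowledge,
and counting it would bias the measure toward what is already recorded.
The product runs over **all** vertices of the path, endpoints included —
so a concept's own abstractness scales every closeness it takes part in;
this follows the formula as stated and is worth remembering when comparing
rows of a relationship matrix. Because reconstruction stops at hub
broadcasts of depth `k`, discovered paths have at most `2k` edges; the
measure is therefore an aggregate over short-to-medium transitive chains,
which is precisely the regime where they are interpretable.

```{r}
net <- toy_type_network() # every toy concept is leaf-level, g = 1
closeness(idx, g, net, "b", "d") # two 2-edge paths, product 1 each
```

## Relationship matrices, thresholding and threshold transfer

`relationship_matrix()` evaluates `R` for every pair of two concept sets
(rows × columns); `distance_matrix()` does the same with hop distances.
Cells pairing a concept with itself carry a SELF marker (stored `NA`):
self-closeness is undefined and SELF cells are excluded from all
thresholding and percentile computations. Unreachable pairs are `Inf` in
distance matrices and simply contribute 0 closeness. `export_matrix()`
writes the flat CSV/JSON "heatmap" artifacts (SELF as an empty cell,
unreachable as `"inf"`), and `autoplot()` renders a ggplot heatmap.

`binarize()` converts a closeness matrix to 0/1 at a threshold δ
(inclusive ≥, so sweeping δ upward can only turn cells off — the ones-count
is monotone non-increasing). From a binary disease × gene matrix,
`shared_neighbor_weights()` builds the ranked relation list `T`: each
disease pair weighted by the number of genes both link to, zero-weight
pairs omitted, sorted by weight with a deterministic lexicographic
tie-break (the fold-enrichment cut depends on rank order, so ties must
break reproducibly).

Closeness scales differ between weighting schemes, so a δ chosen for one
matrix is meaningless on another. `percentile_match_threshold()` transfers
stringency instead of magnitude: it finds the threshold for the target
matrix that passes the same *fraction* of entries as δ passes in the
reference matrix (m-th largest entry, `m = round(frac × n)`, half away
from zero; when nothing should pass it returns one unit above the target
maximum). The round trip preserves the passing fraction to within one
entry of rounding.

## Fold-enrichment crossvalidation

To validate a ranked relation list `T` against an external reference set
`S`, with `S' = S ∩ T` (unordered pair matching):

$$f(\alpha) = \frac{|S'(\alpha)|\,/\,|S'|}{|T(\alpha)|\,/\,|T|},$$

where `T(α)` is the top α % of the ranking — cutoff
`m = round(α·|T|/100)`, half away from zero, floored at one rank so the
cut is never empty — and `S'(α)` counts the reference pairs among them. A
random ranking gives `f ≈ 1` at every α (the suite verifies the resampled
null mean to within three standard errors over 500 replicates); values
well above 1 at small α mean the externally confirmed pairs concentrate at
the top of the ranking; and `f(100) = 1` identically whenever `S'` is
non-empty.

```{r}
ex <- worked_example()
fold_enrichment(ex$t, ex$s, 20)
glance(enrichment_curve(ex$t, ex$s, seq(10, 100, 10)))
```

On this ten-pair example the curve rises from 0 (α = 10: the single
top-ranked pair is not in `S`) to its maximum 2.0 at α = 50 and decays to
1 at α = 100. A worked-example maximum of 3.75 at α = 40 is sometimes
quoted for data of this shape; no rounding convention for the cutoff
(floor, ceiling, or half-away rounding) reproduces it from the formula
above — at α = 40 the top-4 cut contains three of the four `S'` pairs,
giving (3/4)/(4/10) = 1.875 — so this package documents the formula's
actual value and treats the half-away-from-zero cutoff (which reproduces
the α = 20 value 1.25 exactly) as canonical.

## Visualizing shortest-path networks

`layered_layout()` arranges the shortest paths between two query concepts
(take `shortest_subset()` of a path collection first) into columns: layer
`k` holds every vertex at distance `k` from the source along those paths,
drawn at `x = k`, members lexicographically ordered at unit spacing
centered on zero. A vertex on several paths is drawn once, so shared
vertices and edges are visible. Since all laid-out paths have equal
length, layering from the source or the target is equivalent; the source
side is used. `export_layout()` serializes to deterministic JSON (nodes
with coordinates, edges with relation labels) or Graphviz DOT with
`rank=same` constraints; `autoplot()` draws the network directly.

## The synthetic graph generator

`generate_synthetic_graph(n, mean_degree, type_network, seed)` emulates
the one structural property the index depends on: a heavy-tailed degree
distribution, via preferential attachment with an out-degree sequence that
realizes exactly `round(n·mean_degree/2)` edges for any (even fractional)
target mean degree. Concepts receive one or two semantic types sampled
uniformly from the supplied type network, and edges generic relation
labels. It does **not** emulate semantic locality (real relations connect
semantically nearby concepts), the actual UMLS relation vocabulary, its
community structure, or its scale (~2M vertices). Passing tests on
synthetic graphs therefore certify the algorithmic guarantees — exactness
within `k`, path validity, determinism, scaling behavior — not the
biomedical quality of closeness values on real data, which depends on the
curated content of the input thesaurus.

## Numerical and design choices

* **Undirected by default.** Thesaurus relations typically come in
  symmetric pairs; path discovery treats edges as undirected and keeps the
  labels (merged across parallel edges) for display. Self-loops are
  rejected; parallel edges merge.
* **Determinism everywhere.** Lexicographic tie-breaks in hub selection,
  BFS expansion, ranked-relation ordering and layer ordering; a fixed seed
  makes the generator byte-reproducible.
* **Broadcast with the hub present.** Broadcasting before removal is what
  makes the within-`k` exactness guarantee provable; broadcasting after
  removal would lose the hub's own sub-distances.
* **Rounding.** All rank cutoffs round half away from zero (base R's
  `round()` is banker's rounding and would cut differently at .5).
* **Degenerate inputs.** Empty path collections lay out as errors (there
  is nothing to draw); `u = v` queries return distance 0 and no paths;
  empty reference intersections make fold enrichment an error rather than
  a silent 0/0.
* **Problem sizes.** The test suite exercises 200 random graphs of up to
  50 vertices against a BFS oracle for the exactness guarantee, 50 random
  DAGs against a longest-path oracle for levels, 500 null resamples for
  the enrichment baseline, and one end-to-end run on a 5,000-vertex,
  20,000-edge synthetic graph at `k = 6`.

## Limitations

* Labels are held in memory as plain R structures; the package targets
  subset- and study-scale graphs (up to ~10^4–10^5 vertices), not the full
  ~2M-vertex Metathesaurus, which requires an out-of-core engine.
* One predecessor per record means path *counts* are lower bounds on the
  number of simple paths; closeness values are comparable across pairs
  under the same index but are not an exhaustive path census.
* Concept lookup is by exact identifier; mapping free-text terms to
  concept ids is out of scope.
* Directed-relation traversal, incremental index updates after graph
  edits, and licensed-data bundling (UMLS, OMIM, CTD) are out of scope.
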