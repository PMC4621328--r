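---
title: "Integrating hierarchical ontologies by maximum cohesion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating hierarchical ontologies by maximum cohesion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontofuse)
```

## The problem

Biomedical ontologies — GO, drug terminologies, most UMLS sources — are
(or are routinely flattened into) rooted trees of concept terms connected
by child-to-parent `is_a`-like edges. Given two such trees $T_A$, $T_B$
and an externally supplied non-negative closeness matrix $M_{AB}$ over
their term pairs, ontofuse builds one merged tree whose nodes co-locate
at most one term per source. Two requirements drive everything:

1. **LCA preservation.** For any two terms $x, y$ of one source, the node
   that is their lowest common ancestor in the merged tree must contain
   their lowest common ancestor in that source. This is what keeps the
   source taxonomies readable inside the merged structure: if two disease
   terms only share "disease" in their source, no merged arrangement may
   pretend they already share "cancer".
2. **Maximum cohesion.** Among all LCA-preserving integrations, maximise
   the *cohesion* $f = \sum_X M(X)$, the summed closeness of the term
   pairs co-located in each node $X$ (a node holding a single term
   contributes 0). We write $g(T_A, T_B)$ for the attainable maximum.

ontofuse computes closeness for nothing: the matrix is an input (in
practice produced by path-based UMLS mining or any term-similarity
pipeline), and nothing requires its entries to stay below 1.

## The subtree-pair recurrence

Deleting the root of a tree leaves a forest of child subtrees. Two facts
give the problem optimal substructure:

* Either the two roots merge (gaining $M(r_a, r_b)$ plus the best
  integration of the two child forests), or one root stays out, in which
  case the whole of one tree integrates with a single child subtree of
  the other — anything else would give the merged tree two roots.
* A tree of one forest can integrate with at most one tree of the other
  forest, otherwise an LCA violation is forced. Integrating two forests
  is therefore a weighted bipartite *matching* over their subtree pairs,
  with $g$ values as edge weights.

So with $g$ known for all deeper pairs,

$$g(T_i, T_j) = \max\big(M(i,j) + \mathrm{Match}(F_i, F_j),\;
\max_{y \in F_j} g(T_i, T_y),\; \max_{x \in F_i} g(T_x, T_j)\big),$$

where $F_i$ is the child forest of $i$. `build_cohesion_matrix()` fills
the $(n{+}1)\times(m{+}1)$ table of these values in reverse topological
order (children before parents; the order is the reverse of the
deterministic BFS vertex indexing). Index 0 is a *virtual root*: a
super-root above the real root with zero closeness to everything. It
lets entry $(0,0)$ — the full problem — share the same recurrence as
every subproblem.

Two matching kernels stand behind `Match`:

* `matcher = "optimal"`: maximum weighted bipartite matching (the
  assignment problem, solved by igraph). Entry $(0,0)$ is then the exact
  optimum $g(T_A, T_B)$.
* `matcher = "greedy"` (default): scan edges heaviest first, take an
  edge when both endpoints are free. A maximal matching built this way
  carries at least half the optimal matching weight, which propagates
  through the recurrence: the greedy entry $(0,0)$ is at least
  $\tfrac12 g(T_A,T_B)$, at $O(n^2\log n)$ total cost instead of the
  Hungarian $O(n^3)$ per level. Both bounds are property-tested; the
  half bound is also re-measured across the acceptance sweep.

```{r}
t_a <- ontology_tree(data.frame(child = c("a1", "a2"),
                                parent = c("a0", "a0")), id = "A")
t_b <- ontology_tree(data.frame(child = c("b1", "b2"),
                                parent = c("b0", "b0")), id = "B")
cl <- closeness_matrix(
  data.frame(a = c("a0", "a1", "a2", "a1"),
             b = c("b0", "b1", "b2", "b2"),
             s = c(1, 2, 3, 4)), t_a, t_b)
build_cohesion_matrix(t_a, t_b, cl, matcher = "optimal")
```

### Reconstruction without stored choices

Storing per-entry integration details would cost $O(n^3)$ memory, so
`build_integrated_ontology()` rebuilds the tree from the score table
alone: a queue of subtree-pair triples is processed breadth-first and at
each one the case attaining the stored value is re-derived — replaying
the *same* deterministic matcher. This only works because every kernel
breaks ties identically on every call (weight descending, then left and
right vertex index ascending; zero-weight edges are never taken). The
re-derivation prefers cases in the fixed order merge, descend-right,
descend-left; any order would be score-equivalent. Case equality is
checked within $10^{-9}$ (the compiled and reference paths replay
bit-identical arithmetic; the tolerance only matters when a matrix from
one path is reconstructed by the other). The reconstructed tree's total
cohesion equals entry $(0,0)$, and the test suite re-verifies this from
scratch via `cohesion_of()` on every instance it touches.

Zero-closeness pairs are skipped in matchings — merging them gains
nothing and constrains descendants — but the recurrence itself can still
merge a zero-closeness pair when their descendants profit, which is
exactly the behaviour wanted for abstract top-level terms.

### The top-down heuristic

`heuristic_integrate()` is the cheap alternative: after pairing the
virtual roots it walks $T_A$ top-down and greedily picks, for each
vertex $a$, a partner among the *allowable* candidates in $T_B$ — the
still-free descendants of the partner of $a$'s nearest merged ancestor,
minus every branch already claimed by another part of the mapping (once
a vertex merges into a branch, that whole branch is closed to everything
except that vertex's own descendants; anything less strict breaks LCA
preservation). Deep merges close many branches, so the choice maximises
$M(a,b)/\beta^{\mathrm{rdepth}(b)}$, where rdepth counts depth below the
shallowest allowable candidate. `beta = 1` ignores depth; `beta = Inf`
only ever merges at the shallowest level; the paper-style sweet spot in
our benchmarks is around the mean branching factor (`beta = 6` for
trees with about six children per internal vertex). Merges require
strictly positive closeness — both conventions (positivity and measuring
rdepth inside the current candidate set) are our choices where prose
left the details open, picked so that the two $\beta$ extremes behave as
described. The heuristic's result is LCA-preserving by construction but
can be far below the optimum; it exists for ontologies too large for the
quadratic table.

## More than two ontologies

For $k$ trees with a closeness matrix per pair, the cohesion of a node
becomes the sum over all co-located member pairs,
$\mathrm{weight}(X) = \sum_{u,v \in X,\ \sigma(u)<\sigma(v)}
M_{\sigma(u)\sigma(v)}(u,v)$, with $\sigma$ the source-ontology id. A
$k$-dimensional table would cost $O(n^k)$, so all strategies reduce to
pairwise steps plus *closeness merging*: after integrating $T_X$, a
merged node $Z$ relates to an outside term $c$ with
$\sum_{v \in Z} M_{\sigma(v),\cdot}(v, c)$ (`merge_closeness()`).

`integrate_multi()` offers three contraction orders:

* **basic** — fold in input order. No cohesion information used;
  cheapest ($k{-}1$ pairwise runs).
* **greedy** — keep an inter-ontology score table and always integrate
  the best-scoring active pair, rescoring the newcomer afterwards. The
  score is the *adjusted* cohesion: the cross weight increase divided by
  $|X||Y|$, the product of member-ontology counts. Undivided scores grow
  with size, which would make the process degenerate into always
  extending the current largest object.
* **fast** — score all pairs once, then contract the maximum-weight edge
  $k{-}1$ times; parallel edges collapse to the larger stale weight and
  nothing is ever rescored. The justification is monotonicity: a merged
  ontology can only gain cohesion against an outsider, so each stale
  value is a lower bound. Consequently the total cohesion is at least
  the maximum-spanning-tree weight of the initial score graph, which is
  at least $1/(k{-}1)$ of the optimum when the pairwise steps are exact
  (with the greedy matcher the package checks the spanning-tree bound
  itself rather than claiming the constant). When the maximum remaining
  weight is 0, contraction still proceeds (smallest-id pair) so the
  output is always a single tree.

The contraction order and parallel-edge rule are our reconstruction of a
procedure whose pseudocode figure is not machine-readable in the source;
the maximum-stale-weight rule is the only reading under which the
spanning-tree bound goes through, and it makes the contraction sequence
exactly Kruskal's algorithm on the initial score graph.

## Oracles and validation

Guarantees are only as good as their checks, so the package carries its
own test bedrock:

* `validate_criterion1()` — exhaustive LCA-preservation check over all
  within-source vertex pairs of any integration.
* `exhaustive_pair_optimum()` — the recurrence evaluated with
  brute-force enumeration of every forest matching (no assignment solver
  involved), guarded to tiny trees.
* A second, structurally different pair oracle (internal) enumerates all
  partial injections between the vertex sets that preserve ancestor
  order and are closed under LCAs. That realizability characterisation
  is our own derivation, so it is cross-validated against the recursion
  oracle rather than trusted alone — the two agreeing on random
  instances is the strongest guard against a shared systematic error.
* `exhaustive_multi_optimum()` — joint brute force over group partitions
  of forests (at most one subtree per source per group), guarded to
  $k \le 3$, $n \le 4$.
* `max_spanning_tree_weight()` — the fast strategy's lower bound.

## The synthetic benchmark

`benchmark_suite()` reproduces the study conditions used throughout the
tests: each ontology is the minimum spanning tree of a symmetric
uniform(0,1) random matrix, rooted at the first vertex and oriented
away from it, and every cross-ontology term pair draws an independent
uniform(0,1) closeness. With i.i.d. uniform weights, minimum versus
maximum spanning tree is a relabelling, so the choice cannot bias
results; the root placement is arbitrary but fixed. Replicate $r$ of a
suite is seeded `seed + r - 1`, and all generators restore the caller's
RNG state, so there is no hidden global randomness.

What this emulates — and what it does not: uniform random topologies
have no power-law branching, no depth imbalance and no correlation
between closeness and structure, all of which real GO/drug-terminology
pairs have. Passing bounds on these instances therefore demonstrates the
*algorithmic* guarantees (optimality, the half bound, the spanning-tree
bound, LCA preservation), not retrieval quality on any real ontology
pair.

Problem sizes used by the checks are chosen to exercise each claim at
the smallest scale where it is meaningful: 200 random pairs of 2–7
vertices for exact-versus-oracle agreement and the half bound, 100
instances of three 4-vertex trees for the $1/(k{-}1)$ bound, and suites
up to $k = 10$, $n = 500$ (10 replicates per size) for the contraction
bound and the strategy comparison.

## Numerical and design choices

* Scores are IEEE doubles; matchings and reconstruction replay identical
  arithmetic, so equality checks are exact on a single path with a
  $10^{-9}$ tolerance for cross-path checks. All guarantees are
  closed-form inequalities checked with the same tolerance.
* Vertex indices are dense BFS numbers with lexicographic sibling order:
  every matching, tie-break and reconstruction is reproducible across
  runs and machines.
* The score-table entry $(i,j)$ is interpreted as $g$ of the two rooted
  *subtrees* — the reading consistent with the leaf base case
  $g = M(n, m)$ — and entry $(0,0)$ with virtual roots equals entry of
  the real root pair, which the merge-first reconstruction relies on.
* Inputs must be trees. DAG-shaped hierarchies (shared subterms) must be
  expanded into independent concepts by the caller first;
  `read_mrhier_paths()` rejects conflicting parentage for this reason.
* The compiled (Rcpp) path implements the greedy-matcher table and
  reconstruction for scale; a reference R implementation parameterised
  by an arbitrary matcher is kept alongside and tested equal on random
  instances.

## Known limitations

* Quality beyond the proven bounds depends on the contraction order. On
  dense uniform closeness at larger sizes ($k = 10$, $n \ge 100$), the
  benchmark comparison in the acceptance suite finds the plain input-order
  fold attaining slightly (1–3%) higher mean cohesion than the
  guided fast contraction, while at small sizes the guided orders win —
  so the orderings reported for guided strategies in the literature
  should not be assumed scale-independent. The proven bounds
  (spanning-tree, $1/(k{-}1)$) hold everywhere and are what the package
  guarantees.
* The adjusted-cohesion rescoring makes the greedy strategy roughly a
  factor $k$ slower than fast; the package exposes both rather than
  recommending one.
* Closeness matrices are dense in memory ($n_a \times n_b$ doubles per
  pair); for $k = 10$, $n = 500$ that is ~90 MB of inputs, fine on a
  laptop, but very large ontology collections need a sparse rework.
* No attempt is made to decide whether a pair of ontologies is
  *meaningfully* integrable; a cohesion score exists for any inputs.
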