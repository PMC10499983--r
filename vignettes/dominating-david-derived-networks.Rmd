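---
title: "Dominating David derived networks: exact construction, indices, and the closed-form audit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominating David derived networks: exact construction, indices, and the closed-form audit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dddnet)
```

## Scope and model

This package computes degree-based topological indices for the dominating
David derived network family. A degree-based index of a simple graph $G$
is $\sum_{uv \in E(G)} f(\eta(u), \eta(v))$ for a symmetric weight $f$;
the three built-in weights are the forgotten index
($f(a,b) = a^2 + b^2$), the second Zagreb index ($f(a,b) = ab$) and the
hyper-Zagreb index ($f(a,b) = (a+b)^2$). Because every member of the
family has maximum degree 4, an index is determined by the *degree-pair
edge partition* — the count $|E_{a,b}|$ of edges whose endpoint degrees
are $\{a, b\}$ — and for a parametric family those counts are quadratics
in the dimension $t$, so each index has an exact closed form
$c_2 t^2 + c_1 t + c_0$.

Everything in the package is exact integer/rational arithmetic. There is
no floating point in any computation that affects a result; doubles only
carry exact integers (all magnitudes here are far below $2^{53}$).

## The geometric construction

`build_ddd(t)` composes six steps: build the honeycomb HC($t$) (the
centered hexagon-of-hexagons, $3t^2-3t+1$ cells, $6t^2$ vertices,
$9t^2-3t$ edges); subdivide every edge; join, inside each hexagonal cell,
the edge midpoints at distance 4 along the subdivided 12-cycle — the six
chords trace the two overlapping triangles of a hexagram; planarize by
placing a vertex at every chord crossing; delete the original honeycomb
vertices and their incident edges; and subdivide every horizontal edge.

Three design choices make this exact and reproducible:

* **Flat-top orientation.** Hexagons are drawn with two horizontal edges,
  which is what makes "horizontal edge" in the final step well defined.
  Horizontality is tested as exact equality of $y$-coordinates.
* **Sheared rational coordinates.** A point stored as $(x, y)$ sits at
  Euclidean position $(x, \sqrt3\,y)$. The shear is linear, so midpoints
  and segment intersections computed on the stored rationals agree with
  the Euclidean picture, while every coordinate stays rational — the
  irrational $\sqrt3$ of the hexagonal lattice never enters the
  arithmetic. The lattice is scaled so a hexagon has circumradius 4, at
  which point *every* construction point (corner, midpoint, crossing,
  horizontal split) has integer coordinates. Crossings are merged by
  exact coordinate equality; there is no epsilon anywhere, and a degenerate
  concurrency of three or more chords would merge into a single vertex.
* **Canonical identifiers.** A vertex id is its origin tag plus its exact
  coordinates; vertices and edges are ordered lexicographically by
  coordinate. Two builds of the same network are `identical()`.

## The derived types

The published account of this family defines D₁, D₂, D₃ only through
drawings of the $t = 2$ case, so the transformation rules had to be
reconstructed and are treated as hypotheses to be audited, not assumed:

* **D₁** joins every pair of degree-2 horizontal-split vertices that are
  vertically one hexagon side apart with no vertex at the segment
  midpoint. On the lattice the only free midpoints are cell centres and
  the positions of deleted honeycomb corners; every other vertical
  candidate is blocked by a crossing or an edge-midpoint vertex. Each
  split vertex can satisfy the rule at most once (the opposite direction
  is always blocked), so the added edges are pairwise disjoint and become
  exactly the (3,3) class.
* **D₂** subdivides every (3,3) edge of D₁. This is forced by the
  partition tables themselves: the D₂ table has no (3,3) entry, agrees
  with D₁ on (2,2), (2,4), (3,4), (4,4), and its (2,3) frequency equals
  D₁'s (2,3) plus twice D₁'s (3,3) — the algebraic signature of
  subdividing all (3,3) edges ($4t-4 + 2(9t^2-13t+5) = 18t^2-22t+6$,
  checked symbolically in the tests).
* **D₃** replaces each D₁ joining edge by two parallel length-2 paths
  through fresh vertices, taking the paired splits to degree 4 and keeping
  all degrees in $\{2, 4\}$.

`audit_construction(t)` measures the partition of each constructed type
and compares it with the built-in parametric tables; the test suite runs
it for $t = 1..4$ and every entry matches:

```{r}
audit_construction(2)
```

Since the drawings themselves are not machine-readable, this
partition-level agreement — together with the step-by-step count
contracts — is the verification that the reconstructed rules produce the
intended family.

## The index engine and its dual routes

`index_from_graph()` sums edge by edge; `index_from_partition()` sums
count × weight over a partition. The two must agree on every graph, and
the suite enforces this on all fixtures and all constructed networks up to
$t = 4$. Weights are validated for symmetry and integrality on degrees up
to 10 when registered; user weights extend the registry.

The second Zagreb index deserves a note: the published definition for this
family is printed as a *sum* of endpoint degrees, but every published
worked computation and every published numeric value uses the *product*.
The package implements the product (the classical form) and records the
definitional inconsistency here and in the audit rather than in code.

## Closed forms, fitting, and the audit

`expand_index()` multiplies each frequency polynomial by its weight and
collects coefficients exactly. `fit_quadratic_counts()` is the
independent route: interpolate a quadratic through the first three
$(t, \text{count})$ points by Cramer's rule on the integer Vandermonde
system, then certify by requiring exactly zero residual at every remaining
point (at least four points are required; a constant sequence certifies as
a degenerate quadratic, a cubic fails certification). The residual test is
done on integers ($D\,y_k - (N_2 t_k^2 + N_1 t_k + N_0)$), so
certification is never a tolerance decision.

`printed_closed_forms()` stores the nine published final polynomials
verbatim — including the three erroneous ones and the published
second-Zagreb line for D₃ whose middle term lacks its factor $t$
(normalised to $-1872t$ for evaluation, the only reading consistent with
the published numeric table; the raw string is preserved). The audit:

```{r}
audit_closed_forms()
```

The derived side of every row is confirmed by the interpolation oracle in
the tests, so the three mismatches — the forgotten and hyper-Zagreb
closed forms for D₁ and the hyper-Zagreb closed form for D₂ — are
internal contradictions of the published account, not artifacts of this
implementation. Which lineage the original authors intended as
authoritative is unknowable from the source, so the package never
adjudicates: `reproduce_comparison()` evaluates both lineages side by side
and flags disagreeing cells.

```{r}
head(reproduce_comparison(2), 9)
```

All nine partition-derived sequences increase strictly in $t$ (tested for
$t = 1..10$), consistent with the qualitative claim published alongside
the tables.

## Parameters, defaults, and problem sizes

* `t` — the only model parameter: cells per honeycomb side
  (dimensionless). Tables are valid for $t \ge 1$ (adopted from the
  published numeric range; every frequency is non-negative there, checked
  to $t = 50$).
* `reproduce_comparison(t_max = 6)` mirrors the published range; any
  larger `t_max` works.
* The lattice scale (circumradius 4) is fixed, not a tuning knob: it is
  the smallest scale making all construction points integral.
* The test suite constructs networks up to $t = 4$ (D₂(4) has ~1200
  edges), which already exercises every boundary/interior vertex class of
  the family; construction cost grows as $O(t^2)$ cells and is a few
  seconds at $t = 6$.

## Limitations

* The derived-type rules are reconstructions from degree accounting and
  lattice geometry; they reproduce the published partitions exactly for
  $t = 1..4$ and the package audits (rather than assumes) agreement at
  any other $t$.
* The segment-intersection engine handles the hexagram-chord case (and
  concurrent-chord degeneracies); it is not a general planar overlay.
* Indices here are degree-based only; distance-based indices are out of
  scope.
* No QSPR/QSAR regression is included: the published account asserts
  correlations with the acentric factor and entropy but supplies no data
  or formulas for them.
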