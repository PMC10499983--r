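# dddnet

Exact construction and degree-based topological-index analysis of
dominating David derived networks.

## The problem

In chemical graph theory a molecular structure is modelled as a simple
graph and summarised by *topological indices* — numeric invariants used as
molecular descriptors in QSPR/QSAR work. For a graph *G* with degree
function η(v), the three degree-based indices this package centres on are

- the forgotten index **F\*(G) = Σ_{uv∈E} [η(u)² + η(v)²]**,
- the second Zagreb index **M₂\*(G) = Σ_{uv∈E} η(u)·η(v)**,
- the hyper-Zagreb index **HM(G) = Σ_{uv∈E} [η(u) + η(v)]²**.

The graphs of interest are the *dominating David derived networks*: start
from the honeycomb network HC(t) (a hexagon-of-hexagons with t cells per
side), subdivide every edge, draw the hexagram (Star of David) chords in
every cell, planarize the chord crossings, delete the original honeycomb
skeleton, and subdivide every horizontal edge. That yields DDD(t), from
which three derived types D₁(t), D₂(t), D₃(t) are obtained. For each type
the edge set splits into classes E₍a,b₎ by the endpoint degrees (a, b),
with class sizes that are quadratics in t — e.g. for D₁(t):

| (a,b)  | (2,2) | (2,3) | (2,4)  | (3,3)      | (3,4)        | (4,4)        |
|--------|-------|-------|--------|------------|--------------|--------------|
| count  | 4t    | 4t−4  | 28t−16 | 9t²−13t+5  | 36t²−56t+24  | 36t²−52t+20  |

so every index has a closed form c₂t² + c₁t + c₀.

`dddnet` provides:

- an exact geometric constructor for HC(t), DDD(t), D₁, D₂, D₃ on a
  rational lattice (no floating point anywhere: chord crossings are exact
  segment intersections, merged by exact coordinate equality, so builds are
  bit-for-bit reproducible);
- degree-pair partition extraction and the built-in parametric tables;
- an index engine with a pluggable symmetric weight registry, computing
  either edge-by-edge on a graph or from a partition (the two routes agree
  everywhere, a tested invariant);
- exact expansion of parametric tables into closed-form quadratics,
  interpolation-based fitting with certification from brute-force counts;
- an **audit**: the published closed forms for this family contain internal
  errors (three of the nine final polynomials contradict the very partition
  tables they were expanded from, and the published definition of M₂\* is
  printed as a sum while every published computation uses the product).
  The audit reports both lineages coefficient-by-coefficient instead of
  silently correcting either.

## Worked example

```r
library(dddnet)

d3 <- derive_type3(build_ddd(2))
d3
#> labeled_graph: 144 vertices, 228 edges
#>   vertex tags: crossing=42, horizontal-split=42, midpoint=30, parallel-path=30
#>   degrees:     2:60, 4:84

degree_pair_partition(d3)
#> degree-pair edge partition (228 edges)
#>  a b count
#>  2 2     8
#>  2 4   104
#>  4 4   116

index_from_graph(d3, "hm")
#> [1] 11296

expand_index(ddd_partition_tables("d3"), "hm")
#> 5904t^2 - 7568t + 2816          # evaluates to 11296 at t = 2

audit_closed_forms()
#> closed-form audit: derived (from partition tables) vs published
#>   MISMATCH d1  FN_STAR derived 2214t^2 - 2654t + 958        published 2214t^2 - 1951t + 958
#>   ok       d1  M2_STAR derived 1089t^2 - 1357t + 501        published 1089t^2 - 1357t + 501
#>   MISMATCH d1  HM_N    derived 4392t^2 - 5368t + 1960       published 4392t^2 - 5362t + 3240
#>   ok       d2  FN_STAR derived 2286t^2 - 2758t + 998        published 2286t^2 - 2758t + 998
#>   ...
```

The measured partition of the constructed D₃(2) matches the parametric
table exactly (104 = 36·4−20·2, 116 = 72·4−108·2+44), and the graph-route
index equals the closed form at t = 2. `audit_construction(t)` runs that
comparison for all three families at any t.

A command-line wrapper is installed as `exec/dddnet`:

```sh
Rscript exec/dddnet index --family d2 --t 1 --index fn --from table   # 526
Rscript exec/dddnet build --family d3 --t 2 --out d3.graphml --format graphml
Rscript exec/dddnet audit --out audit.csv
Rscript exec/dddnet verify --tmax 6 --out comparison.csv --plot comparison.png
```

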