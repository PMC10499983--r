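#' Derived network types D1(t), D2(t), D3(t)
#'
#' The three derived types refine DDD(t) (see [build_ddd()]):
#'
#' * **D1(t)** ([derive_type1()]): every pair of degree-2 horizontal-split
#'   vertices that are vertically one hexagon side apart, with no vertex at
#'   the midpoint of the connecting segment, is joined by an edge.  On the
#'   construction lattice the free midpoints are exactly the hexagon
#'   centres and the positions of the deleted original honeycomb vertices;
#'   everywhere else the candidate segment is blocked by a crossing or an
#'   edge-midpoint vertex.  The rule is purely geometric, and the degree-pair
#'   partition of the result is *measured* and audited against the built-in
#'   parametric table for D1 rather than assumed (see
#'   [audit_construction()]).
#' * **D2(t)** ([derive_type2()]): obtained from D1(t) by subdividing once
#'   every edge whose two endpoints both have degree 3.  This is the unique
#'   elementary move consistent with the published partition tables: the D2
#'   table has no (3,3) entry and its (2,3) frequency equals the D1 (2,3)
#'   frequency plus twice the D1 (3,3) frequency — the signature of
#'   subdividing all (3,3) edges.
#' * **D3(t)** ([derive_type3()]): instead of a single joining edge, every
#'   D1 candidate pair is connected by two parallel paths of length 2
#'   through fresh vertices (tagged `parallel-path`), so the paired split
#'   vertices reach degree 4 and all degrees stay in \{2, 4\}.
#'
#' @param ddd the output of [build_ddd()]
#' @param d1 for [derive_type2()]: a `labeled_graph`, normally the output of
#'   [derive_type1()] (any simple graph works; only (3,3) edges are touched)
#' @return a `labeled_graph`
#' @examples
#' d1 <- derive_type1(build_ddd(1))
#' degree_pair_partition(d1)
#' @export
derive_type1 <- function(ddd) {
  stopifnot(inherits(ddd, "labeled_graph"))
  pairs <- vertical_split_pairs(ddd)
  out <- labeled_graph(ddd$vertices,
                       rbind(ddd$edges,
                             data.frame(from = pairs$a, to = pairs$b,
                                        stringsAsFactors = FALSE)))
  attr(out, "t") <- attr(ddd, "t")
  attr(out, "family") <- "d1"
  check_graph_invariants(out)
}

#' @rdname derive_type1
#' @export
derive_type2 <- function(d1) {
  stopifnot(inherits(d1, "labeled_graph"))
  deg <- graph_degrees(d1)
  rows <- which(deg[d1$edges$from] == 3L & deg[d1$edges$to] == 3L)
  out <- subdivide_edge_rows(d1, rows, "midpoint")
  attr(out, "t") <- attr(d1, "t")
  attr(out, "family") <- "d2"
  out
}

#' @rdname derive_type1
#' @export
derive_type3 <- function(ddd) {
  stopifnot(inherits(ddd, "labeled_graph"))
  pairs <- vertical_split_pairs(ddd)
  if (!nrow(pairs)) return(ddd)
  # two parallel length-2 paths per pair, through new vertices placed one
  # lattice unit left/right of the (free) segment midpoint
  lx <- rat_add(pairs$mxn, pairs$mxd, -1, 1)
  rx <- rat_add(pairs$mxn, pairs$mxd, 1, 1)
  pl <- vertex_id("p", lx$n, lx$d, pairs$myn, pairs$myd)
  pr <- vertex_id("p", rx$n, rx$d, pairs$myn, pairs$myd)
  newv <- data.frame(id = c(pl, pr), tag = "parallel-path",
                     xn = c(lx$n, rx$n), xd = c(lx$d, rx$d),
                     yn = c(pairs$myn, pairs$myn), yd = c(pairs$myd, pairs$myd),
                     stringsAsFactors = FALSE)
  if (any(newv$id %in% ddd$vertices$id)) stop("parallel-path vertex collides with an existing vertex")
  newe <- data.frame(from = c(pairs$a, pl, pairs$a, pr),
                     to   = c(pl, pairs$b, pr, pairs$b),
                     stringsAsFactors = FALSE)
  out <- labeled_graph(rbind(ddd$vertices, newv), rbind(ddd$edges, newe))
  attr(out, "t") <- attr(ddd, "t")
  attr(out, "family") <- "d3"
  check_graph_invariants(out)
}

# Candidate pairs for the D1/D3 refinement: degree-2 horizontal-split
# vertices (u, v) with equal x, vertical separation of 2 lattice units
# (one hexagon side, Euclidean sqrt(3) x side/2 scaling aside), and no
# vertex of any kind at the segment midpoint.  Each pair is reported once.
vertical_split_pairs <- function(g) {
  v <- g$vertices
  deg <- graph_degrees(g)
  occupied <- vertex_coord_keys(g)
  splits <- which(v$tag == "horizontal-split" & deg[v$id] == 2L)
  if (anyNA(v$xn[splits])) stop("split vertices must carry coordinates")
  split_key <- stats::setNames(v$id[splits], occupied[splits])

  out <- data.frame(a = character(), b = character(),
                    mxn = numeric(), mxd = numeric(),
                    myn = numeric(), myd = numeric(),
                    stringsAsFactors = FALSE)
  if (!length(splits)) return(out)

  up1 <- rat_add(v$yn[splits], v$yd[splits], 1, 1)   # midpoint height
  up2 <- rat_add(v$yn[splits], v$yd[splits], 2, 1)   # partner height
  partner_key <- coord_key(v$xn[splits], v$xd[splits], up2$n, up2$d)
  mid_key <- coord_key(v$xn[splits], v$xd[splits], up1$n, up1$d)
  ok <- partner_key %in% names(split_key) & !(mid_key %in% occupied)
  if (!any(ok)) return(out)
  data.frame(a = v$id[splits][ok],
             b = unname(split_key[partner_key[ok]]),
             mxn = v$xn[splits][ok], mxd = v$xd[splits][ok],
             myn = up1$n[ok], myd = up1$d[ok],
             stringsAsFactors = FALSE)
}
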