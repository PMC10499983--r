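#' Derivation pipeline: from HC(t) to the dominating David derived network
#'
#' The dominating David derived network DDD(t) is obtained from the
#' honeycomb HC(t) by six deterministic steps:
#'
#' 1. build HC(t) ([build_honeycomb()]);
#' 2. subdivide every edge once ([subdivide_all_edges()]);
#' 3. inside each hexagonal cell, join midpoint vertices at distance 4
#'    along the subdivided 12-cycle, tracing the two overlapping triangles
#'    of a hexagram ([add_star_chords()]);
#' 4. planarize: place a new vertex at every chord crossing
#'    ([insert_crossing_vertices()]);
#' 5. delete the original honeycomb vertices and their incident edges
#'    ([delete_original_skeleton()]);
#' 6. subdivide every horizontal edge once
#'    ([subdivide_horizontal_edges()]).
#'
#' All geometry is exact: crossings are computed by rational segment
#' intersection and merged by exact coordinate equality, so re-running a
#' build yields the identical labeled graph.
#'
#' @param t positive integer dimension
#' @return [build_ddd()] returns the DDD(t) `labeled_graph` (every vertex
#'   tagged `midpoint`, `crossing` or `horizontal-split`; every degree 2 or
#'   4).  The step functions return the intermediate `labeled_graph`s.
#' @examples
#' g <- build_ddd(1)
#' graph_order(g)  # 18
#' graph_size(g)   # 24
#' @export
build_ddd <- function(t) {
  t <- check_dimension(t)
  g <- build_honeycomb(t)
  g <- subdivide_all_edges(g)
  g <- add_star_chords(g)
  g <- insert_crossing_vertices(g)
  g <- delete_original_skeleton(g)
  g <- subdivide_horizontal_edges(g)
  attr(g, "t") <- t
  attr(g, "family") <- "ddd"
  g
}

# ---- step 2 -------------------------------------------------------------

#' @rdname build_ddd
#' @param g a `labeled_graph` (for [add_star_chords()], the Step-2 output
#'   carrying a `cells` attribute)
#' @export
subdivide_all_edges <- function(g) {
  stopifnot(inherits(g, "labeled_graph"))
  out <- subdivide_edge_rows(g, seq_len(graph_size(g)), "midpoint")
  attr(out, "cells") <- attr(g, "cells")
  out
}

# Replace the given edge rows by two half-edges through a fresh midpoint.
subdivide_edge_rows <- function(g, rows, tag) {
  if (!length(rows)) return(g)
  v <- g$vertices
  idx <- stats::setNames(seq_len(nrow(v)), v$id)
  e <- g$edges[rows, , drop = FALSE]
  a <- idx[e$from]; b <- idx[e$to]

  has_xy <- !anyNA(v$xn[a]) && !anyNA(v$xn[b])
  if (has_xy) {
    mx <- rat_mid(v$xn[a], v$xd[a], v$xn[b], v$xd[b])
    my <- rat_mid(v$yn[a], v$yd[a], v$yn[b], v$yd[b])
    mid_id <- vertex_id(tag_code(tag), mx$n, mx$d, my$n, my$d)
    newv <- data.frame(id = mid_id, tag = tag,
                       xn = mx$n, xd = mx$d, yn = my$n, yd = my$d,
                       stringsAsFactors = FALSE)
  } else {
    mid_id <- sprintf("%s[%s|%s]", tag_code(tag), e$from, e$to)
    newv <- data.frame(id = mid_id, tag = tag,
                       xn = NA_real_, xd = 1, yn = NA_real_, yd = 1,
                       stringsAsFactors = FALSE)
  }
  if (anyDuplicated(mid_id)) stop("subdivision produced colliding midpoint identifiers")

  keep <- g$edges[setdiff(seq_len(graph_size(g)), rows), , drop = FALSE]
  half <- data.frame(from = c(e$from, mid_id), to = c(mid_id, e$to),
                     stringsAsFactors = FALSE)
  check_graph_invariants(
    labeled_graph(rbind(v, newv), rbind(keep, half))
  )
}

# ---- step 3 -------------------------------------------------------------

#' @rdname build_ddd
#' @param cells list of 6-cycles of original-vertex ids (defaults to the
#'   `cells` attribute carried through from [build_honeycomb()])
#' @export
add_star_chords <- function(g, cells = attr(g, "cells")) {
  stopifnot(inherits(g, "labeled_graph"))
  if (is.null(cells)) stop("no hexagonal cells available: pass `cells` or build via build_honeycomb()")
  v <- g$vertices
  idx <- stats::setNames(seq_len(nrow(v)), v$id)
  key2id <- stats::setNames(v$id, vertex_coord_keys(g))
  ekey <- paste(g$edges$from, g$edges$to)

  chord_from <- character(); chord_to <- character(); chord_cell <- integer()
  for (ci in seq_along(cells)) {
    cc <- cells[[ci]]
    if (length(cc) != 6 || !all(cc %in% v$id)) {
      stop("cell ", ci, " is not a hexagon over known vertices")
    }
    a <- idx[cc]; b <- idx[cc[c(2:6, 1)]]
    mx <- rat_mid(v$xn[a], v$xd[a], v$xn[b], v$xd[b])
    my <- rat_mid(v$yn[a], v$yd[a], v$yn[b], v$yd[b])
    mids <- key2id[coord_key(mx$n, mx$d, my$n, my$d)]
    if (anyNA(mids)) {
      stop("cell ", ci, " boundary is not a subdivided 12-cycle (missing midpoint vertices)")
    }
    # 12-cycle = corner, midpoint, corner, ...; midpoint pairs at cycle
    # distance 4 are two apart in the midpoint sequence
    f <- mids; s <- mids[c(3:6, 1:2)]
    half_a <- paste(cc, mids); half_b <- paste(mids, cc[c(2:6, 1)])
    both <- c(ekey, paste(g$edges$to, g$edges$from))
    if (!all(c(half_a, half_b) %in% both)) {
      stop("cell ", ci, " boundary is not a subdivided 12-cycle (missing half-edges)")
    }
    chord_from <- c(chord_from, f)
    chord_to <- c(chord_to, s)
    chord_cell <- c(chord_cell, rep(ci, 6))
  }

  out <- labeled_graph(v, rbind(g$edges,
                                data.frame(from = chord_from, to = chord_to,
                                           stringsAsFactors = FALSE)))
  attr(out, "cells") <- cells
  attr(out, "chords") <- data.frame(from = chord_from, to = chord_to,
                                    cell = chord_cell, stringsAsFactors = FALSE)
  check_graph_invariants(out)
}

# ---- step 4 -------------------------------------------------------------

#' @rdname build_ddd
#' @param chords data.frame (`from`, `to`, `cell`) naming the Step-3 chord
#'   edges; defaults to the attribute left by [add_star_chords()]
#' @export
insert_crossing_vertices <- function(g, chords = attr(g, "chords")) {
  stopifnot(inherits(g, "labeled_graph"))
  if (is.null(chords)) stop("no chord record available: run add_star_chords() first")
  v <- g$vertices
  idx <- stats::setNames(seq_len(nrow(v)), v$id)
  if (anyNA(v$xn[idx[c(chords$from, chords$to)]])) {
    stop("chord endpoints must carry exact coordinates")
  }

  # accumulate, per chord, the interior intersection points (exact) and
  # their position parameter along the chord for later ordering
  n_ch <- nrow(chords)
  hits <- vector("list", n_ch)  # each: data.frame(key, sx n/d, pt coords)
  add_hit <- function(i, s, px, py) {
    hits[[i]][[length(hits[[i]]) + 1]] <<- list(
      sn = s$n, sd = s$d, xn = px$n, xd = px$d, yn = py$n, yd = py$d)
  }
  for (i in seq_len(n_ch)) hits[[i]] <- list()

  coords <- function(id) {
    k <- idx[[id]]
    list(xn = v$xn[k], xd = v$xd[k], yn = v$yn[k], yd = v$yd[k])
  }

  for (cell in unique(chords$cell)) {
    rows <- which(chords$cell == cell)
    for (ii in seq_along(rows)) {
      for (jj in seq_len(ii - 1L)) {
        i <- rows[ii]; j <- rows[jj]
        p1 <- coords(chords$from[i]); p2 <- coords(chords$to[i])
        p3 <- coords(chords$from[j]); p4 <- coords(chords$to[j])
        inter <- segment_intersection(p1, p2, p3, p4)
        if (!is.null(inter)) {
          add_hit(i, inter$s, inter$x, inter$y)
          add_hit(j, inter$u, inter$x, inter$y)
        }
      }
    }
  }

  if (all(vapply(hits, length, 1L) == 0L)) return(g)

  # collect distinct crossing points by exact coordinate equality
  allpts <- do.call(rbind, lapply(hits, function(h) {
    if (!length(h)) return(NULL)
    do.call(rbind, lapply(h, function(z) data.frame(z, stringsAsFactors = FALSE)))
  }))
  pkey <- coord_key(allpts$xn, allpts$xd, allpts$yn, allpts$yd)
  upts <- allpts[!duplicated(pkey), , drop = FALSE]
  xid <- vertex_id("x", upts$xn, upts$xd, upts$yn, upts$yd)
  newv <- data.frame(id = xid, tag = "crossing",
                     xn = upts$xn, xd = upts$xd, yn = upts$yn, yd = upts$yd,
                     stringsAsFactors = FALSE)
  if (any(xid %in% v$id)) stop("crossing point coincides with an existing vertex")

  # replace each chord by its split segments
  ekey_all <- paste(g$edges$from, g$edges$to)
  ckey1 <- paste(chords$from, chords$to)
  ckey2 <- paste(chords$to, chords$from)
  chord_rows <- which(ekey_all %in% c(ckey1, ckey2))
  keep <- g$edges[-chord_rows, , drop = FALSE]

  seg_from <- character(); seg_to <- character()
  for (i in seq_len(n_ch)) {
    h <- hits[[i]]
    if (!length(h)) {
      seg_from <- c(seg_from, chords$from[i]); seg_to <- c(seg_to, chords$to[i])
      next
    }
    hd <- do.call(rbind, lapply(h, function(z) data.frame(z, stringsAsFactors = FALSE)))
    hd <- hd[!duplicated(coord_key(hd$xn, hd$xd, hd$yn, hd$yd)), , drop = FALSE]
    hd <- hd[order(rat_num(hd$sn, hd$sd)), , drop = FALSE]
    ids <- vertex_id("x", hd$xn, hd$xd, hd$yn, hd$yd)
    chain <- c(chords$from[i], ids, chords$to[i])
    seg_from <- c(seg_from, chain[-length(chain)])
    seg_to <- c(seg_to, chain[-1])
  }

  out <- labeled_graph(rbind(v, newv),
                       rbind(keep, data.frame(from = seg_from, to = seg_to,
                                              stringsAsFactors = FALSE)))
  attr(out, "cells") <- attr(g, "cells")
  check_graph_invariants(out)
}

# Proper (open-segment) intersection of p1p2 with p3p4, exact rationals.
# Returns NULL if the open segments do not cross; otherwise the point and
# the position parameters s (along p1p2) and u (along p3p4).
segment_intersection <- function(p1, p2, p3, p4) {
  sub2 <- function(a, b) list(x = rat_sub(a$xn, a$xd, b$xn, b$xd),
                              y = rat_sub(a$yn, a$yd, b$yn, b$yd))
  d1 <- sub2(p2, p1); d2 <- sub2(p4, p3); w <- sub2(p3, p1)
  cross <- function(u, v) {
    a <- rat_mul(u$x$n, u$x$d, v$y$n, v$y$d)
    b <- rat_mul(u$y$n, u$y$d, v$x$n, v$x$d)
    rat_sub(a$n, a$d, b$n, b$d)
  }
  den <- cross(d1, d2)
  if (den$n == 0) return(NULL)                  # parallel or collinear
  cw2 <- cross(w, d2); cw1 <- cross(w, d1)
  s <- rat_div(cw2$n, cw2$d, den$n, den$d)
  u <- rat_div(cw1$n, cw1$d, den$n, den$d)
  strict01 <- function(r) r$n > 0 & (r$d - r$n) > 0   # 0 < n/d < 1, d > 0
  if (!strict01(s) || !strict01(u)) return(NULL)
  sx <- rat_mul(s$n, s$d, d1$x$n, d1$x$d)
  sy <- rat_mul(s$n, s$d, d1$y$n, d1$y$d)
  list(s = s, u = u,
       x = rat_add(p1$xn, p1$xd, sx$n, sx$d),
       y = rat_add(p1$yn, p1$yd, sy$n, sy$d))
}

# ---- step 5 -------------------------------------------------------------

#' @rdname build_ddd
#' @export
delete_original_skeleton <- function(g) {
  stopifnot(inherits(g, "labeled_graph"))
  drop <- g$vertices$id[g$vertices$tag == "original-honeycomb"]
  if (!length(drop)) return(labeled_graph(g$vertices, g$edges))
  v <- g$vertices[!(g$vertices$id %in% drop), , drop = FALSE]
  e <- g$edges[!(g$edges$from %in% drop | g$edges$to %in% drop), , drop = FALSE]
  check_graph_invariants(labeled_graph(v, e))
}

# ---- step 6 -------------------------------------------------------------

#' @rdname build_ddd
#' @export
subdivide_horizontal_edges <- function(g) {
  stopifnot(inherits(g, "labeled_graph"))
  v <- g$vertices
  idx <- stats::setNames(seq_len(nrow(v)), v$id)
  a <- idx[g$edges$from]; b <- idx[g$edges$to]
  if (anyNA(v$xn[a]) || anyNA(v$xn[b])) {
    stop("horizontal-edge subdivision needs exact coordinates")
  }
  horiz <- which(rat_eq(v$yn[a], v$yd[a], v$yn[b], v$yd[b]))
  subdivide_edge_rows(g, horiz, "horizontal-split")
}
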