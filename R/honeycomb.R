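#' Build a honeycomb network HC(t)
#'
#' HC(t) is the centered hexagon-of-hexagons: hexagonal cells arranged in a
#' hexagonal block with `t` cells along each side, so HC(1) is a single
#' hexagon, HC(2) the seven-cell flower, HC(3) the nineteen-cell block, and
#' in general `3t^2 - 3t + 1` cells, `6t^2` vertices and `9t^2 - 3t` edges.
#' Hexagons are drawn flat-top (two horizontal edges), which fixes the
#' meaning of "horizontal edge" for the later pipeline steps.
#'
#' Coordinates are exact integers on the sheared lattice described in
#' [labeled_graph()]: each cell has circumradius 4 in lattice units, chosen
#' so that every construction point of the full derivation pipeline
#' (edge midpoints, hexagram chord crossings, horizontal splits) lands on
#' integer coordinates.
#'
#' @param t positive integer dimension (cells per side)
#' @return A `labeled_graph` whose vertices are all tagged
#'   `original-honeycomb`, with attribute `cells`: a list of character
#'   vectors, each the 6-cycle of vertex ids bounding one hexagonal cell in
#'   cyclic order.
#' @examples
#' hc <- build_honeycomb(2)
#' graph_order(hc)        # 24
#' graph_size(hc)         # 30
#' length(attr(hc, "cells"))  # 7
#' @export
build_honeycomb <- function(t) {
  t <- check_dimension(t)

  # axial cell coordinates of the centered hexagonal arrangement
  qr <- expand.grid(q = -(t - 1):(t - 1), r = -(t - 1):(t - 1))
  qr <- qr[abs(qr$q + qr$r) <= t - 1, , drop = FALSE]

  # flat-top lattice: cell centre and the 6 corner offsets (cyclic order)
  cx <- 6 * qr$q
  cy <- 2 * qr$q + 4 * qr$r
  off_x <- c(4, 2, -2, -4, -2, 2)
  off_y <- c(0, 2, 2, 0, -2, -2)

  n_cells <- nrow(qr)
  vx <- rep(cx, each = 6) + rep(off_x, n_cells)
  vy <- rep(cy, each = 6) + rep(off_y, n_cells)
  ids <- vertex_id("o", vx, 1, vy, 1)

  cells <- split(ids, factor(rep(seq_len(n_cells), each = 6),
                             levels = seq_len(n_cells)))
  # order cells bottom-left to top-right for reproducible output
  cells <- cells[order(cy, cx)]
  names(cells) <- NULL

  keep <- !duplicated(ids)
  vertices <- data.frame(id = ids[keep], tag = "original-honeycomb",
                         xn = vx[keep], xd = 1, yn = vy[keep], yd = 1,
                         stringsAsFactors = FALSE)

  from <- unlist(lapply(cells, function(cc) cc))
  to <- unlist(lapply(cells, function(cc) cc[c(2:6, 1)]))
  key <- ifelse(from < to, paste(from, to), paste(to, from))
  keep_e <- !duplicated(key)
  g <- labeled_graph(vertices, data.frame(from = from[keep_e], to = to[keep_e],
                                          stringsAsFactors = FALSE))
  attr(g, "cells") <- cells
  check_graph_invariants(g)
  g
}

check_dimension <- function(t) {
  if (length(t) != 1 || is.na(t) || !is.numeric(t) || t != round(t) || t < 1) {
    stop("the dimension t must be a single integer >= 1, got: ",
         deparse(substitute(t)), " = ", paste(t, collapse = ","))
  }
  as.integer(t)
}
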