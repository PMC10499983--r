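#' Labeled planar graphs with exact rational coordinates
#'
#' `labeled_graph()` is the container every constructor in this package
#' returns: a simple undirected graph whose vertices carry a stable
#' identifier, an origin tag recording which construction step created them,
#' and (optionally) exact rational planar coordinates.  Coordinates are
#' stored in sheared lattice units: the true Euclidean position of a vertex
#' is `(x, sqrt(3) * y)`.  The shear is linear, so midpoints, collinearity
#' and segment intersections computed on the stored rationals agree exactly
#' with the Euclidean picture, while every coordinate stays rational.
#'
#' @param vertices data frame with columns `id` (character, unique), `tag`
#'   (character origin tag), and exact rational coordinates as four numeric
#'   columns `xn, xd, yn, yd` (numerator/denominator pairs; `NA` numerators
#'   mark vertices without an embedding).
#' @param edges data frame with character columns `from`, `to` referring to
#'   vertex ids.  Edges are undirected; orientation and order are
#'   canonicalised.
#' @return An object of class `labeled_graph`.
#' @examples
#' v <- data.frame(id = c("a", "b"), tag = "generic",
#'                 xn = c(0, 1), xd = 1, yn = 0, yd = 1)
#' g <- labeled_graph(v, data.frame(from = "a", to = "b"))
#' graph_order(g)
#' @export
labeled_graph <- function(vertices, edges) {
  stopifnot(is.data.frame(vertices), is.data.frame(edges))
  need <- c("id", "tag", "xn", "xd", "yn", "yd")
  miss <- setdiff(need, names(vertices))
  if (length(miss)) stop("vertices is missing columns: ", paste(miss, collapse = ", "))
  vertices <- vertices[, need]
  vertices$id <- as.character(vertices$id)
  vertices$tag <- as.character(vertices$tag)
  if (anyDuplicated(vertices$id)) stop("duplicate vertex identifiers")

  if (nrow(edges)) {
    edges <- data.frame(from = as.character(edges$from),
                        to   = as.character(edges$to),
                        stringsAsFactors = FALSE)
    bad <- setdiff(c(edges$from, edges$to), vertices$id)
    if (length(bad)) stop("edges reference unknown vertices: ", paste(utils::head(bad, 3), collapse = ", "))
    if (any(edges$from == edges$to)) stop("self-loops are not allowed")
  } else {
    edges <- data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  }

  # canonical vertex order: lexicographic by exact coordinate, then id
  ord <- order(rat_num(vertices$xn, vertices$xd),
               rat_num(vertices$yn, vertices$yd),
               vertices$id, method = "radix", na.last = TRUE)
  vertices <- vertices[ord, , drop = FALSE]
  rownames(vertices) <- NULL

  if (nrow(edges)) {
    rank <- stats::setNames(seq_len(nrow(vertices)), vertices$id)
    swap <- rank[edges$from] > rank[edges$to]
    tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
    edges <- edges[order(rank[edges$from], rank[edges$to]), , drop = FALSE]
    if (anyDuplicated(paste(edges$from, edges$to))) stop("parallel edges are not allowed")
    rownames(edges) <- NULL
  }

  structure(list(vertices = vertices, edges = edges), class = "labeled_graph")
}

#' @rdname labeled_graph
#' @param g a `labeled_graph`
#' @export
graph_order <- function(g) nrow(g$vertices)

#' @rdname labeled_graph
#' @export
graph_size <- function(g) nrow(g$edges)

#' Vertex degrees
#'
#' @param g a `labeled_graph`
#' @return Named integer vector of degrees, one entry per vertex, in the
#'   graph's canonical vertex order.
#' @export
graph_degrees <- function(g) {
  d <- stats::setNames(integer(nrow(g$vertices)), g$vertices$id)
  if (nrow(g$edges)) {
    tab <- table(c(g$edges$from, g$edges$to))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

# exact-coordinate lookup key ("xn/xd|yn/yd" reduced form)
coord_key <- function(xn, xd, yn, yd) {
  paste(rat_fmt(xn, xd), rat_fmt(yn, yd), sep = "|")
}

vertex_coord_keys <- function(g) {
  with(g$vertices, coord_key(xn, xd, yn, yd))
}

# canonical vertex id from tag code + exact coordinates
vertex_id <- function(code, xn, xd, yn, yd) {
  sprintf("%s(%s,%s)", code, rat_fmt(xn, xd), rat_fmt(yn, yd))
}

tag_code <- function(tag) {
  c("original-honeycomb" = "o", "midpoint" = "m", "crossing" = "x",
    "horizontal-split" = "s", "parallel-path" = "p", "generic" = "v")[tag]
}

# internal sanity check: simplicity + handshake lemma
check_graph_invariants <- function(g) {
  stopifnot(sum(graph_degrees(g)) == 2L * graph_size(g))
  invisible(g)
}

#' @export
print.labeled_graph <- function(x, ...) {
  tags <- table(x$vertices$tag)
  cat(sprintf("labeled_graph: %d vertices, %d edges\n", graph_order(x), graph_size(x)))
  cat("  vertex tags:", paste(sprintf("%s=%d", names(tags), tags), collapse = ", "), "\n")
  dg <- table(graph_degrees(x))
  cat("  degrees:    ", paste(sprintf("%s:%d", names(dg), dg), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.labeled_graph <- function(object, ...) {
  structure(list(order = graph_order(object), size = graph_size(object),
                 tags = table(object$vertices$tag),
                 degree_table = table(graph_degrees(object))),
            class = "summary.labeled_graph")
}

#' @export
print.summary.labeled_graph <- function(x, ...) {
  cat(sprintf("order %d, size %d\n", x$order, x$size))
  print(x$degree_table)
  invisible(x)
}

#' Plot a labeled graph using its stored coordinates
#'
#' Draws edges as segments and vertices as points at their Euclidean
#' positions (`x`, `sqrt(3) * y`).  Graphs without coordinates cannot be
#' plotted this way.
#'
#' @param x a `labeled_graph` with coordinates
#' @param vertex.cex point size
#' @param ... passed to [graphics::plot()]
#' @export
plot.labeled_graph <- function(x, vertex.cex = 0.6, ...) {
  v <- x$vertices
  if (anyNA(v$xn)) stop("graph has vertices without coordinates; cannot plot")
  px <- rat_num(v$xn, v$xd)
  py <- sqrt(3) * rat_num(v$yn, v$yd)
  graphics::plot(px, py, asp = 1, pch = 16, cex = vertex.cex,
                 xlab = "", ylab = "", axes = FALSE, ...)
  idx <- stats::setNames(seq_len(nrow(v)), v$id)
  graphics::segments(px[idx[x$edges$from]], py[idx[x$edges$from]],
                     px[idx[x$edges$to]],   py[idx[x$edges$to]], col = "grey40")
  graphics::points(px, py, pch = 16, cex = vertex.cex)
  invisible(x)
}

#' Convert to an igraph object
#'
#' Vertex attributes `tag`, `x`, `y` (Euclidean, numeric) are carried over.
#'
#' @param g a `labeled_graph`
#' @return an [igraph::graph] object
#' @export
as_igraph <- function(g) {
  v <- g$vertices
  vd <- data.frame(name = v$id, tag = v$tag,
                   x = rat_num(v$xn, v$xd),
                   y = sqrt(3) * rat_num(v$yn, v$yd),
                   stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(g$edges, directed = FALSE, vertices = vd)
}

#' Graph import/export
#'
#' `write_edgelist()` writes a two-column tab-separated edge list with a
#' header line; `read_edgelist()` reads one back as a coordinate-free
#' `labeled_graph` (tag `generic`).  `write_graphml()` exports through
#' igraph with coordinate attributes.
#'
#' @param g a `labeled_graph`
#' @param path file path
#' @return `read_edgelist()` returns a `labeled_graph`; the writers return
#'   `path` invisibly.
#' @export
write_edgelist <- function(g, path) {
  utils::write.table(g$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  e <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = "character", comment.char = "")
  if (!all(c("from", "to") %in% names(e))) {
    names(e)[1:2] <- c("from", "to")
  }
  ids <- sort(unique(c(e$from, e$to)))
  v <- data.frame(id = ids, tag = "generic",
                  xn = NA_real_, xd = 1, yn = NA_real_, yd = 1,
                  stringsAsFactors = FALSE)
  labeled_graph(v, e[, c("from", "to")])
}

#' @rdname write_edgelist
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(as_igraph(g), path, format = "graphml")
  invisible(path)
}

# quick generic graph builder used by fixtures and tests
graph_from_edges <- function(from, to) {
  ids <- sort(unique(c(from, to)))
  v <- data.frame(id = ids, tag = rep("generic", length(ids)),
                  xn = rep(NA_real_, length(ids)), xd = rep(1, length(ids)),
                  yn = rep(NA_real_, length(ids)), yd = rep(1, length(ids)),
                  stringsAsFactors = FALSE)
  labeled_graph(v, data.frame(from = from, to = to, stringsAsFactors = FALSE))
}
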