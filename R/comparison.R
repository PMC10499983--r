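#' Reproduce the numerical index comparison for the three families
#'
#' Evaluates all nine (family, index) combinations for `t = 1..t_max`
#' through both lineages: the partition lineage (index computed from the
#' built-in parametric tables) and the published lineage (the printed
#' closed forms evaluated as published).  Cells where the two disagree are
#' flagged — for the three combinations whose published polynomials are
#' internally inconsistent the flags are expected and informative.
#'
#' @param t_max largest dimension (default 6, the published range)
#' @return data frame of class `ddd_comparison` with columns `t`, `family`,
#'   `index`, `partition_value`, `printed_value`, `match`.
#' @examples
#' cmp <- reproduce_comparison(2)
#' subset(cmp, t == 1 & family == "d2" & index == "FN_STAR")$partition_value  # 526
#' @export
reproduce_comparison <- function(t_max = 6) {
  t_max <- check_dimension(t_max)
  tabs <- ddd_partition_tables()
  printed <- printed_closed_forms()
  grid <- expand.grid(t = seq_len(t_max), i = seq_len(nrow(printed)))
  out <- data.frame(
    t = grid$t,
    family = printed$family[grid$i],
    index = printed$index[grid$i],
    stringsAsFactors = FALSE)
  out$partition_value <- mapply(function(t, fam, ind) {
    index_from_partition(evaluate_parametric(tabs[[fam]], t), ind)
  }, out$t, out$family, out$index)
  out$printed_value <- printed$c2[grid$i] * out$t^2 +
    printed$c1[grid$i] * out$t + printed$c0[grid$i]
  out$match <- out$partition_value == out$printed_value
  out <- out[order(out$t, out$family, out$index), ]
  rownames(out) <- NULL
  class(out) <- c("ddd_comparison", "data.frame")
  out
}

#' @export
print.ddd_comparison <- function(x, ...) {
  cat("index comparison, partition lineage vs published closed forms\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @rdname reproduce_comparison
#' @param cmp a `ddd_comparison`
#' @param path file path
#' @export
write_comparison_csv <- function(cmp, path) {
  utils::write.csv(as.data.frame(cmp), path, row.names = FALSE)
  invisible(path)
}

#' Plot the index comparison
#'
#' A simple multi-series line chart of the partition-lineage values against
#' `t`, one series per (family, index) combination, log-scaled vertical
#' axis.
#'
#' @param x a `ddd_comparison`
#' @param ... passed on to [graphics::matplot()]
#' @export
plot.ddd_comparison <- function(x, ...) {
  series <- paste(x$family, x$index, sep = ".")
  wide <- stats::reshape(data.frame(t = x$t, series = series, v = x$partition_value),
                         idvar = "t", timevar = "series", direction = "wide")
  wide <- wide[order(wide$t), ]
  m <- as.matrix(wide[, -1, drop = FALSE])
  graphics::matplot(wide$t, m, type = "b", pch = 1:9, lty = 1, log = "y",
                    xlab = "t", ylab = "index value", ...)
  graphics::legend("topleft", legend = sub("^v\\.", "", colnames(m)),
                   pch = 1:9, lty = 1, col = 1:6, cex = 0.7, bty = "n")
  invisible(x)
}

#' Deterministic fixture graphs
#'
#' Small named graphs with well-known partitions and index values, used
#' throughout the test suite: paths, cycles, stars, complete graphs, a
#' single hexagon, and the first two honeycombs.
#'
#' @return named list of `labeled_graph`s
#' @examples
#' degree_pair_partition(fixture_graphs()$C6)
#' @export
fixture_graphs <- function() {
  cyc <- function(n) graph_from_edges(sprintf("v%02d", 1:n), sprintf("v%02d", c(2:n, 1)))
  pth <- function(n) graph_from_edges(sprintf("v%02d", 1:(n - 1)), sprintf("v%02d", 2:n))
  star <- function(k) graph_from_edges(rep("hub", k), sprintf("v%02d", 1:k))
  cmpl <- function(n) {
    pr <- utils::combn(sprintf("v%02d", 1:n), 2)
    graph_from_edges(pr[1, ], pr[2, ])
  }
  list(P4 = pth(4), C6 = cyc(6), C12 = cyc(12), S4 = star(4),
       K4 = cmpl(4), K5 = cmpl(5),
       HEX = build_honeycomb(1), HC2 = build_honeycomb(2))
}
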