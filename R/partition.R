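#' Degree-pair edge partitions
#'
#' The central bookkeeping device for degree-based indices: for every edge
#' uv the unordered pair of endpoint degrees `(a, b)`, `a <= b`, is tallied,
#' so that an index of the form sum over edges of `f(deg u, deg v)` becomes
#' a weighted sum over the partition.
#'
#' @param g a `labeled_graph`
#' @return A `degree_partition`: a data frame with integer columns `a`, `b`
#'   (sorted ascending, each unordered pair at most once) and `count`,
#'   whose counts sum to the number of edges of `g`.
#' @examples
#' hc <- build_honeycomb(2)
#' degree_pair_partition(hc)
#' @export
degree_pair_partition <- function(g) {
  stopifnot(inherits(g, "labeled_graph"))
  deg <- graph_degrees(g)
  if (!graph_size(g)) return(degree_partition(integer(), integer(), integer()))
  da <- deg[g$edges$from]; db <- deg[g$edges$to]
  a <- pmin(da, db); b <- pmax(da, db)
  tab <- table(a, b)
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  df <- df[df$Freq > 0, , drop = FALSE]
  degree_partition(as.integer(df$a), as.integer(df$b), as.integer(df$Freq))
}

degree_partition <- function(a, b, count) {
  stopifnot(length(a) == length(b), length(b) == length(count),
            all(a <= b), all(count >= 0))
  key <- paste(a, b)
  if (anyDuplicated(key)) stop("duplicate degree pairs in partition")
  ord <- order(a, b)
  structure(data.frame(a = as.integer(a[ord]), b = as.integer(b[ord]),
                       count = count[ord]),
            class = c("degree_partition", "data.frame"))
}

#' @export
print.degree_partition <- function(x, ...) {
  cat("degree-pair edge partition (", sum(x$count), " edges)\n", sep = "")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Serialize a partition to CSV
#'
#' Columns `a, b, count`, fixed order, no row names — byte-stable across
#' runs.
#'
#' @param p a `degree_partition`
#' @param path file path
#' @export
write_partition_csv <- function(p, path) {
  utils::write.csv(as.data.frame(p), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- parametric partitions ---------------------------------------------

#' Parametric edge-partition tables for the derived network families
#'
#' Each family's edge partition is a list of degree pairs with a frequency
#' that is an exact quadratic in the dimension `t`.  `ddd_partition_tables()`
#' returns the built-in reference tables for D1(t), D2(t), D3(t):
#'
#' * D1: (2,2) `4t`; (2,3) `4t-4`; (2,4) `28t-16`; (3,3) `9t^2-13t+5`;
#'   (3,4) `36t^2-56t+24`; (4,4) `36t^2-52t+20`
#' * D2: (2,2) `4t`; (2,3) `18t^2-22t+6`; (2,4) `28t-16`;
#'   (3,4) `36t^2-56t+24`; (4,4) `36t^2-52t+20`
#' * D3: (2,2) `4t`; (2,4) `36t^2-20t`; (4,4) `72t^2-108t+44`
#'
#' All frequencies are non-negative for every integer `t >= 1`, the
#' validity domain adopted for all three tables.
#'
#' @param family one of `"d1"`, `"d2"`, `"d3"`, or `NULL` for all three
#' @return A `parametric_partition` (or a named list of the three): fields
#'   `family`, `entries` (data frame `a`, `b`, `c2`, `c1`, `c0` — the
#'   frequency `c2 t^2 + c1 t + c0`), `min_t`.
#' @examples
#' evaluate_parametric(ddd_partition_tables("d3"), 2)
#' @export
ddd_partition_tables <- function(family = NULL) {
  tabs <- list(
    d1 = parametric_partition("d1", rbind(
      c(2, 2,  0,   4,   0),
      c(2, 3,  0,   4,  -4),
      c(2, 4,  0,  28, -16),
      c(3, 3,  9, -13,   5),
      c(3, 4, 36, -56,  24),
      c(4, 4, 36, -52,  20))),
    d2 = parametric_partition("d2", rbind(
      c(2, 2,  0,   4,   0),
      c(2, 3, 18, -22,   6),
      c(2, 4,  0,  28, -16),
      c(3, 4, 36, -56,  24),
      c(4, 4, 36, -52,  20))),
    d3 = parametric_partition("d3", rbind(
      c(2, 2,  0,   4,   0),
      c(2, 4, 36, -20,   0),
      c(4, 4, 72, -108, 44))))
  if (is.null(family)) return(tabs)
  family <- match.arg(tolower(family), names(tabs))
  tabs[[family]]
}

parametric_partition <- function(family, m, min_t = 1L) {
  entries <- data.frame(a = as.integer(m[, 1]), b = as.integer(m[, 2]),
                        c2 = m[, 3], c1 = m[, 4], c0 = m[, 5])
  stopifnot(all(entries$a <= entries$b))
  structure(list(family = family, entries = entries, min_t = min_t),
            class = "parametric_partition")
}

#' @export
print.parametric_partition <- function(x, ...) {
  cat("parametric edge partition: family", x$family,
      sprintf("(valid for t >= %d)\n", x$min_t))
  e <- x$entries
  for (i in seq_len(nrow(e))) {
    cat(sprintf("  (%d,%d): %s\n", e$a[i], e$b[i],
                format(quadratic_poly(e$c2[i], e$c1[i], e$c0[i]))))
  }
  invisible(x)
}

#' Evaluate a parametric partition at an integer dimension
#'
#' @param p a `parametric_partition`
#' @param t integer dimension, at least `p$min_t`
#' @return a `degree_partition` with the exact evaluated counts
#' @export
evaluate_parametric <- function(p, t) {
  stopifnot(inherits(p, "parametric_partition"))
  t <- check_dimension(t)
  if (t < p$min_t) stop("t = ", t, " is below the table's validity domain (t >= ", p$min_t, ")")
  counts <- p$entries$c2 * t^2 + p$entries$c1 * t + p$entries$c0
  if (any(counts < 0)) {
    stop("negative frequency at t = ", t, ": outside the table's validity domain")
  }
  degree_partition(p$entries$a, p$entries$b, counts)
}

#' Serialize a parametric partition to JSON
#'
#' Emits the family name, validity domain, and one record per degree pair
#' carrying the exact quadratic coefficients of its frequency.
#'
#' @param p a `parametric_partition`
#' @param path optional file path; if `NULL`, the JSON string is returned
#' @export
parametric_to_json <- function(p, path = NULL) {
  obj <- list(family = p$family, min_t = p$min_t, entries = p$entries)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
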