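#' Degree-based topological index definitions
#'
#' A degree-based topological index is a graph invariant of the form
#' sum over edges uv of `f(deg u, deg v)` for a symmetric weight `f`.
#' The built-in registry provides the three indices this package centres
#' on:
#'
#' * `FN_STAR` — forgotten index, `f(a,b) = a^2 + b^2`
#' * `M2_STAR` — second Zagreb index, `f(a,b) = a * b`
#' * `HM_N`    — hyper-Zagreb index, `f(a,b) = (a + b)^2`
#'
#' `M2_STAR` uses the classical product form.  The published definition of
#' this index for the present network family is printed as a *sum* of the
#' endpoint degrees, but every worked computation and every tabulated value
#' in the same source uses the product; the audit machinery records this
#' definitional inconsistency (see [audit_closed_forms()]).
#'
#' @param name index name (unique within a registry)
#' @param weight symmetric function of two positive integer degrees
#'   returning a non-negative integer
#' @return `index_definition()` returns an `index_definition` object;
#'   `index_registry()` the named list of built-in definitions, optionally
#'   extended.
#' @examples
#' reg <- index_registry()
#' reg$FN_STAR$weight(2, 4)  # 20
#' @export
index_definition <- function(name, weight) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name), is.function(weight))
  grid <- expand.grid(a = 1:10, b = 1:10)
  w1 <- mapply(weight, grid$a, grid$b)
  w2 <- mapply(weight, grid$b, grid$a)
  if (!all(w1 == w2)) stop("weight function is not symmetric on degrees up to 10")
  if (any(w1 < 0) || any(w1 != round(w1))) {
    stop("weight function must return non-negative integers")
  }
  structure(list(name = name, weight = weight), class = "index_definition")
}

#' @export
print.index_definition <- function(x, ...) {
  cat(sprintf("index %s: f(2,3) = %d, f(3,4) = %d\n",
              x$name, x$weight(2, 3), x$weight(3, 4)))
  invisible(x)
}

#' @rdname index_definition
#' @param extra optional list of additional [index_definition()]s to merge
#'   into the registry; a name clashing with an existing entry is rejected
#' @export
index_registry <- function(extra = NULL) {
  reg <- list(
    FN_STAR = index_definition("FN_STAR", function(a, b) a^2 + b^2),
    M2_STAR = index_definition("M2_STAR", function(a, b) a * b),
    HM_N    = index_definition("HM_N",    function(a, b) (a + b)^2))
  for (d in extra) {
    stopifnot(inherits(d, "index_definition"))
    if (d$name %in% names(reg)) stop("duplicate index name: ", d$name)
    reg[[d$name]] <- d
  }
  reg
}

# resolve a definition from an index_definition or a registry name
resolve_index <- function(d) {
  if (inherits(d, "index_definition")) return(d)
  if (is.character(d) && length(d) == 1) {
    reg <- index_registry()
    key <- toupper(d)
    alias <- c(FN = "FN_STAR", M2 = "M2_STAR", HM = "HM_N")
    if (key %in% names(alias)) key <- alias[[key]]
    if (key %in% names(reg)) return(reg[[key]])
  }
  stop("unknown index: ", deparse(d))
}

#' Compute a degree-based index
#'
#' `index_from_partition()` evaluates the weighted sum over a degree-pair
#' partition; `index_from_graph()` sums edge by edge.  The two routes agree
#' on every graph, which the test suite exercises as the engine's central
#' invariant.  All arithmetic is exact integer arithmetic.
#'
#' @param p a `degree_partition`
#' @param g a `labeled_graph`
#' @param d an `index_definition` or one of the registry names
#'   (`"FN_STAR"`/`"fn"`, `"M2_STAR"`/`"m2"`, `"HM_N"`/`"hm"`)
#' @return a non-negative number (exact integer value)
#' @examples
#' index_from_partition(evaluate_parametric(ddd_partition_tables("d2"), 1), "fn")  # 526
#' @export
index_from_partition <- function(p, d) {
  stopifnot(inherits(p, "degree_partition"))
  d <- resolve_index(d)
  if (!nrow(p)) return(0)
  as.numeric(sum(p$count * mapply(d$weight, p$a, p$b)))
}

#' @rdname index_from_partition
#' @export
index_from_graph <- function(g, d) {
  stopifnot(inherits(g, "labeled_graph"))
  d <- resolve_index(d)
  if (!graph_size(g)) return(0)
  deg <- graph_degrees(g)
  as.numeric(sum(mapply(d$weight, deg[g$edges$from], deg[g$edges$to])))
}
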