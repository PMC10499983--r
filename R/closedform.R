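#' Exact quadratic polynomials in the dimension t
#'
#' The closed form of every index over the built-in partition tables is a
#' quadratic `c2 t^2 + c1 t + c0` with integer coefficients.  Equality is
#' coefficient-wise and evaluation is exact.
#'
#' @param c2,c1,c0 integer coefficients
#' @return an object of class `quadratic_poly`
#' @examples
#' p <- quadratic_poly(2286, -2758, 998)
#' qp_eval(p, 1)  # 526
#' @export
quadratic_poly <- function(c2, c1, c0) {
  co <- c(c2 = unname(c2), c1 = unname(c1), c0 = unname(c0))
  if (anyNA(co) || any(co != round(co))) stop("coefficients must be exact integers")
  structure(co, class = "quadratic_poly")
}

#' @rdname quadratic_poly
#' @param p a `quadratic_poly`
#' @param t integer (vector) at which to evaluate
#' @export
qp_eval <- function(p, t) {
  stopifnot(inherits(p, "quadratic_poly"))
  unname(p["c2"] * t^2 + p["c1"] * t + p["c0"])
}

#' @export
format.quadratic_poly <- function(x, ...) {
  term <- function(c, s) {
    if (c == 0) return(NULL)
    sprintf("%s%s%s", if (c < 0) "- " else "+ ", format(abs(c), scientific = FALSE), s)
  }
  parts <- c(term(x["c2"], "t^2"), term(x["c1"], "t"), term(x["c0"], ""))
  if (is.null(parts)) return("0")
  out <- paste(parts, collapse = " ")
  sub("^\\+ ", "", out)
}

#' @export
print.quadratic_poly <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Expand a parametric partition into a closed-form quadratic
#'
#' Multiplies each degree pair's frequency polynomial by the index weight
#' `f(a, b)` and collects terms with exact integer arithmetic.  Evaluating
#' the result at any `t` equals computing the index on the evaluated
#' partition — the expand/evaluate commutation the tests enforce.
#'
#' @param p a `parametric_partition`
#' @param d an index (see [index_from_partition()])
#' @return a `quadratic_poly`
#' @examples
#' expand_index(ddd_partition_tables("d2"), "fn")  # 2286 t^2 - 2758 t + 998
#' @export
expand_index <- function(p, d) {
  stopifnot(inherits(p, "parametric_partition"))
  d <- resolve_index(d)
  w <- mapply(d$weight, p$entries$a, p$entries$b)
  quadratic_poly(sum(w * p$entries$c2), sum(w * p$entries$c1), sum(w * p$entries$c0))
}

#' Fit and certify a quadratic from brute-force counts
#'
#' Interpolates a quadratic through the first three `(t, count)` points with
#' exact arithmetic (Cramer's rule on the Vandermonde system) and certifies
#' it by checking that every remaining point has zero residual.  At least
#' four points are required — with three there is nothing to certify.  This
#' is the independent closed-form oracle: it never looks at
#' [expand_index()], only at counts measured from constructed graphs (or
#' supplied directly).
#'
#' @param counts either a numeric vector of counts aligned with `t_points`,
#'   or a function of `t`; a function may return a count directly or a
#'   `labeled_graph` (then `index` must name the index to measure on it)
#' @param t_points at least 4 distinct positive integers
#' @param index optional index (see [index_from_partition()]) applied when
#'   `counts` is a graph-building function
#' @return a list of class `quadratic_fit`: `coefficients` (exact, possibly
#'   non-integer rationals returned as numerics), `certified` (TRUE iff all
#'   held-out residuals are exactly zero and the quadratic model holds),
#'   `poly` (a `quadratic_poly` when the coefficients are integers, else
#'   `NULL`), `residuals`.
#' @examples
#' fit_quadratic_counts(function(t) qp_eval(quadratic_poly(1, 0, 5), t), 1:4)
#' @export
fit_quadratic_counts <- function(counts, t_points, index = NULL) {
  t_points <- as.numeric(t_points)
  if (length(t_points) < 4) stop("need at least 4 points: 3 to interpolate, the rest to certify")
  if (anyDuplicated(t_points)) stop("t_points must be distinct")
  if (any(t_points != round(t_points))) stop("t_points must be integers")

  if (is.function(counts)) {
    y <- vapply(t_points, function(t) {
      r <- counts(t)
      if (inherits(r, "labeled_graph")) {
        if (is.null(index)) stop("`index` is required when the builder returns a graph")
        index_from_graph(r, index)
      } else as.numeric(r)
    }, numeric(1))
  } else {
    y <- as.numeric(counts)
    if (length(y) != length(t_points)) stop("counts and t_points lengths differ")
  }

  t3 <- t_points[1:3]; y3 <- y[1:3]
  det3 <- function(m) {
    m[1, 1] * (m[2, 2] * m[3, 3] - m[2, 3] * m[3, 2]) -
    m[1, 2] * (m[2, 1] * m[3, 3] - m[2, 3] * m[3, 1]) +
    m[1, 3] * (m[2, 1] * m[3, 2] - m[2, 2] * m[3, 1])
  }
  V <- cbind(t3^2, t3, 1)
  D <- det3(V)                      # Vandermonde, nonzero for distinct t
  N2 <- det3(cbind(y3, t3, 1))
  N1 <- det3(cbind(t3^2, y3, 1))
  N0 <- det3(cbind(t3^2, t3, y3))

  # integer residual check: D*y(t) - (N2 t^2 + N1 t + N0) must vanish
  rest <- seq_along(t_points)[-(1:3)]
  resid <- D * y[rest] - (N2 * t_points[rest]^2 + N1 * t_points[rest] + N0)
  certified <- all(resid == 0)

  co <- c(c2 = N2 / D, c1 = N1 / D, c0 = N0 / D)
  poly <- if (all(co == round(co))) quadratic_poly(co[1], co[2], co[3]) else NULL
  structure(list(coefficients = co, certified = certified, poly = poly,
                 residuals = stats::setNames(resid / D, t_points[rest])),
            class = "quadratic_fit")
}

#' @export
print.quadratic_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf("quadratic fit: c2 = %g, c1 = %g, c0 = %g (%scertified)\n",
              co[1], co[2], co[3], if (x$certified) "" else "NOT "))
  invisible(x)
}

#' Published closed forms for the derived network families
#'
#' The reference registry of the closed-form quadratics as published for
#' this network family — including the entries whose printed coefficients
#' contradict the same source's own partition tables.  They are reference
#' data, never silently corrected: [audit_closed_forms()] compares them
#' with the exact expansions.  The published second-Zagreb line for D3 is
#' printed with its middle term missing the factor `t`
#' (`1440t^2 - 1872 + 704`); it is normalised here to `-1872 t` for
#' evaluation — the only reading consistent with the published numerical
#' comparison table — with the raw printed string preserved.
#'
#' @return data frame with one row per (family, index): integer columns
#'   `c2`, `c1`, `c0`, the raw `printed` string, and a `note`.
#' @export
printed_closed_forms <- function() {
  df <- data.frame(
    family = rep(c("d1", "d2", "d3"), each = 3),
    index = rep(c("FN_STAR", "M2_STAR", "HM_N"), 3),
    c2 = c(2214, 1089, 4392,   2286, 1116, 4518,   3024, 1440, 5904),
    c1 = c(-1951, -1357, -5362, -2758, -1396, -5055, -3824, -1872, -7568),
    c0 = c(958, 501, 3240,     998, 516, 2030,     1408, 704, 2816),
    stringsAsFactors = FALSE)
  df$printed <- sprintf("%dt^2 %s %st %s %s",
                        df$c2, ifelse(df$c1 < 0, "-", "+"), abs(df$c1),
                        ifelse(df$c0 < 0, "-", "+"), abs(df$c0))
  df$note <- ""
  m2d3 <- df$family == "d3" & df$index == "M2_STAR"
  df$printed[m2d3] <- "1440t^2 - 1872 + 704"
  df$note[m2d3] <- "published middle term lacks its factor t; normalised to -1872t for evaluation"
  df
}
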