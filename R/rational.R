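# Exact rational arithmetic on parallel numerator/denominator vectors.
#
# Numerators and denominators are stored as doubles but always hold exact
# integers; every operation reduces by the gcd so magnitudes stay far below
# 2^53 for the lattice sizes this package builds.  Denominators are kept
# strictly positive, the sign lives on the numerator.  NA coordinates
# (graphs without an embedding) propagate.

rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(nz <- (!is.na(b) & b != 0))) {
    r <- a
    r[nz] <- a[nz] %% b[nz]
    a[nz] <- b[nz]
    b[nz] <- r[nz]
  }
  a[!is.na(a) & a == 0] <- 1
  a
}

rat_reduce <- function(n, d) {
  if (any(!is.na(d) & d == 0)) stop("zero denominator")
  s <- ifelse(d < 0, -1, 1)
  n <- n * s; d <- d * s
  g <- rat_gcd(n, d)
  list(n = n / g, d = d / g)
}

rat_add <- function(n1, d1, n2, d2) rat_reduce(n1 * d2 + n2 * d1, d1 * d2)
rat_sub <- function(n1, d1, n2, d2) rat_reduce(n1 * d2 - n2 * d1, d1 * d2)
rat_mul <- function(n1, d1, n2, d2) rat_reduce(n1 * n2, d1 * d2)
rat_div <- function(n1, d1, n2, d2) {
  if (any(!is.na(n2) & n2 == 0)) stop("division by zero")
  rat_reduce(n1 * d2, d1 * n2)
}

# Exact equality of reduced rationals.
rat_eq <- function(n1, d1, n2, d2) !is.na(n1) & !is.na(n2) & n1 == n2 & d1 == d2

# Midpoint (n1/d1 + n2/d2) / 2.
rat_mid <- function(n1, d1, n2, d2) rat_reduce(n1 * d2 + n2 * d1, 2 * d1 * d2)

# Canonical string form, "3" or "-3/2"; used inside vertex identifiers.
rat_fmt <- function(n, d) {
  k <- max(length(n), length(d))
  n <- rep_len(n, k); d <- rep_len(d, k)
  out <- character(k)
  whole <- !is.na(d) & d == 1
  out[whole] <- sprintf("%.0f", n[whole])
  out[!whole] <- sprintf("%.0f/%.0f", n[!whole], d[!whole])
  out[is.na(n)] <- "NA"
  out
}

# Numeric value (for ordering and plotting only, never for equality tests).
rat_num <- function(n, d) n / d
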