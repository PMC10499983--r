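test_that("D1(1) adds exactly one joining edge, between the two free split vertices", {
  ddd <- build_ddd(1)
  d1 <- derive_type1(ddd)
  expect_identical(graph_size(d1), graph_size(ddd) + 1L)
  expect_identical(graph_order(d1), graph_order(ddd))
  expect_identical(partition_counts(degree_pair_partition(d1)),
                   c("(2,2)" = 4L, "(2,4)" = 12L, "(3,3)" = 1L,
                     "(3,4)" = 4L, "(4,4)" = 4L))
})

test_that("constructed D1, D2, D3 partitions match the parametric tables (audited)", {
  for (t in 1:4) {
    a <- audit_construction(t)
    expect_true(all(a$match),
                info = paste("construction audit mismatch at t =", t))
    # partition totals equal edge counts predicted by the tables
    tot <- tapply(a$expected, a$family, sum)
    expect_identical(unname(tot["d1"]), 81 * t^2 - 85 * t + 29)
    expect_identical(unname(tot["d2"]), 90 * t^2 - 98 * t + 34)
    expect_identical(unname(tot["d3"]), 108 * t^2 - 124 * t + 44)
  }
})

test_that("D3(2) has only degrees {2,4} and the predicted 228 edges", {
  d3 <- derive_type3(build_ddd(2))
  expect_true(all(graph_degrees(d3) %in% c(2L, 4L)))
  expect_identical(graph_size(d3), 228L)
  p <- degree_pair_partition(d3)
  expect_true(all(paste(p$a, p$b) %in% c("2 2", "2 4", "4 4")))
})

test_that("D1(2) degrees stay within {2,3,4}", {
  d1 <- derive_type1(build_ddd(2))
  expect_true(all(graph_degrees(d1) %in% c(2L, 3L, 4L)))
})

test_that("type-2 derivation subdivides exactly the (3,3) edges", {
  set.seed(23)
  found <- 0L
  for (rep in 1:8) {
    g <- random_fixture_graph(10, 0.35)
    if (is.null(g)) next
    deg <- graph_degrees(g)
    p <- partition_counts(degree_pair_partition(g))
    n33 <- unname(p["(3,3)"]); if (is.na(n33)) n33 <- 0L
    out <- derive_type2(g)
    expect_identical(graph_size(out), graph_size(g) + n33)
    q <- partition_counts(degree_pair_partition(out))
    # (3,3) gone; (2,3) grows by twice the old (3,3) count; rest unchanged
    expect_true(is.na(q["(3,3)"]))
    old23 <- unname(p["(2,3)"]); if (is.na(old23)) old23 <- 0L
    new23 <- unname(q["(2,3)"]); if (is.na(new23)) new23 <- 0L
    expect_identical(new23, old23 + 2L * n33)
    others <- setdiff(union(names(p), names(q)), c("(3,3)", "(2,3)"))
    for (k in others) {
      pv <- p[k]; qv <- q[k]
      expect_identical(ifelse(is.na(qv), 0L, unname(qv)),
                       ifelse(is.na(pv), 0L, unname(pv)))
    }
    if (n33 > 0) found <- found + 1L
  }
  expect_gt(found, 0)  # the fixtures did contain (3,3) edges
})

test_that("one isolated (3,3) edge becomes two (2,3) edges", {
  # two degree-3 hubs joined to each other and to leaves
  g <- dddnet:::graph_from_edges(c("u", "u", "u", "w", "w"),
                                 c("w", "l1", "l2", "l3", "l4"))
  out <- derive_type2(g)
  q <- partition_counts(degree_pair_partition(out))
  expect_identical(unname(q["(2,3)"]), 2L)  # the two split halves
  expect_identical(unname(q["(1,3)"]), 4L)  # leaf edges untouched
  expect_true(is.na(q["(3,3)"]))
})

test_that("the symbolic D2 = subdivided-D1 frequency identity holds", {
  # (2,3) of D2 equals (2,3) of D1 plus twice (3,3) of D1, as polynomials
  d1 <- ddd_partition_tables("d1")$entries
  d2 <- ddd_partition_tables("d2")$entries
  pick <- function(e, a, b) unlist(e[e$a == a & e$b == b, c("c2", "c1", "c0")])
  expect_identical(pick(d2, 2, 3), pick(d1, 2, 3) + 2 * pick(d1, 3, 3))
  # all other shared pairs agree
  for (ab in list(c(2, 2), c(2, 4), c(3, 4), c(4, 4))) {
    expect_identical(pick(d2, ab[1], ab[2]), pick(d1, ab[1], ab[2]))
  }
})

test_that("derived networks are reproducible builds", {
  a <- derive_type3(build_ddd(2))
  b <- derive_type3(build_ddd(2))
  expect_identical(a$vertices, b$vertices)
  expect_identical(a$edges, b$edges)
})
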