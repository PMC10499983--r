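test_that("the two-lineage comparison reproduces published cells and flags the rest", {
  cmp <- reproduce_comparison(2)
  cell <- function(t, fam, ix) cmp[cmp$t == t & cmp$family == fam & cmp$index == ix, ]
  c1 <- cell(1, "d2", "FN_STAR")
  expect_identical(c(c1$partition_value, c1$printed_value), c(526, 526))
  expect_true(c1$match)
  c2 <- cell(2, "d3", "HM_N")
  expect_identical(c(c2$partition_value, c2$printed_value), c(11296, 11296))
  expect_true(c2$match)
  c3 <- cell(1, "d1", "FN_STAR")
  expect_identical(c3$printed_value, 1221)
  expect_identical(c3$partition_value, 518)
  expect_false(c3$match)
  # flagged cells are exactly the three audited combinations, at every t
  bad <- unique(paste(cmp$family, cmp$index)[!cmp$match])
  expect_setequal(bad, c("d1 FN_STAR", "d1 HM_N", "d2 HM_N"))
})

test_that("comparison CSV output is byte-stable and plottable", {
  cmp <- reproduce_comparison(3)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_comparison_csv(cmp, f1); write_comparison_csv(cmp, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(length(readLines(f1)), 1L + 9L * 3L)
  pf <- tempfile(fileext = ".pdf")
  grDevices::pdf(pf)
  expect_no_error(plot(cmp))
  grDevices::dev.off()
  expect_true(file.exists(pf))
})

test_that("fixture graphs carry their advertised shapes", {
  fx <- fixture_graphs()
  expect_identical(partition_counts(degree_pair_partition(fx$C6)), c("(2,2)" = 6L))
  expect_identical(partition_counts(degree_pair_partition(fx$K4)), c("(3,3)" = 6L))
  expect_identical(c(graph_order(fx$HC2), graph_size(fx$HC2)), c(24L, 30L))
})

test_that("edge-list and GraphML export round-trip through files", {
  g <- build_honeycomb(1)
  f <- tempfile(fileext = ".tsv")
  write_edgelist(g, f)
  expect_identical(length(readLines(f)), 7L)  # header + 6 edges
  back <- read_edgelist(f)
  expect_identical(graph_size(back), 6L)
  expect_identical(degree_pair_partition(back), degree_pair_partition(g))
  gm <- tempfile(fileext = ".graphml")
  write_graphml(g, gm)
  ig <- igraph::read_graph(gm, format = "graphml")
  expect_equal(igraph::gorder(ig), 6)
  expect_equal(igraph::gsize(ig), 6)
})

test_that("the CLI is a thin shell over the library", {
  out <- capture.output(status <- ddd_cli(c("index", "--family", "d2", "--t", "1",
                                            "--index", "fn", "--from", "table")))
  expect_identical(status, 0L)
  expect_identical(out, "526")

  out <- capture.output(status <- ddd_cli(c("index", "--family", "d3", "--t", "2",
                                            "--index", "hm", "--from", "graph")))
  expect_identical(out, "11296")

  f <- tempfile(fileext = ".tsv")
  expect_identical(ddd_cli(c("build", "--family", "hc", "--t", "1", "--out", f)), 0L)
  expect_identical(length(readLines(f)), 7L)

  f <- tempfile(fileext = ".csv")
  expect_identical(ddd_cli(c("audit", "--out", f)), 0L)
  expect_identical(length(readLines(f)), 10L)  # header + 9 rows

  js <- capture.output(ddd_cli(c("closedform", "--family", "d2", "--index", "fn")))
  obj <- jsonlite::fromJSON(js)
  expect_equal(c(obj$c2, obj$c1, obj$c0), c(2286, -2758, 998))

  # arbitrary-graph mode through an edge list
  el <- tempfile(fileext = ".tsv")
  write_edgelist(fixture_graphs()$C6, el)
  out <- capture.output(ddd_cli(c("index", "--graph", el, "--index", "fn")))
  expect_identical(out, "48")

  # usage errors exit nonzero
  expect_identical(suppressMessages(ddd_cli(c("index", "--family", "nope", "--t",
                                              "1", "--index", "fn"))), 1L)
  expect_identical(suppressMessages(ddd_cli(character())), 2L)
  expect_identical(suppressMessages(ddd_cli(c("frobnicate"))), 2L)
})

test_that("CLI verify writes the comparison and honours config defaults", {
  cfg <- tempfile(); writeLines(c("tmax=2", "format=edgelist"), cfg)
  f <- tempfile(fileext = ".csv")
  expect_identical(ddd_cli(c("verify", "--config", cfg, "--out", f)), 0L)
  expect_identical(length(readLines(f)), 1L + 18L)
  png <- tempfile(fileext = ".png")
  expect_identical(ddd_cli(c("verify", "--tmax", "2", "--out", f, "--plot", png)), 0L)
  expect_true(file.size(png) > 0)
})
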