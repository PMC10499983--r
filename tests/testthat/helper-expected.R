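# Frozen expectations shared across test files.

# closed forms derived by exact hand expansion of the parametric tables
# (frequency polynomial x weight, terms collected), independent of
# expand_index(): these were computed on paper before the code existed.
derived_forms <- list(
  d1 = list(FN_STAR = c(2214, -2654, 958),
            M2_STAR = c(1089, -1357, 501),
            HM_N    = c(4392, -5368, 1960)),
  d2 = list(FN_STAR = c(2286, -2758, 998),
            M2_STAR = c(1116, -1396, 516),
            HM_N    = c(4518, -5550, 2030)),
  d3 = list(FN_STAR = c(3024, -3824, 1408),
            M2_STAR = c(1440, -1872, 704),
            HM_N    = c(5904, -7568, 2816)))

# turn a degree_partition into a canonical named count vector
partition_counts <- function(p) {
  stats::setNames(p$count, paste0("(", p$a, ",", p$b, ")"))
}

# random simple graph fixture via igraph, fixed by the caller's seed
random_fixture_graph <- function(n, p) {
  ig <- igraph::sample_gnp(n, p)
  el <- igraph::as_edgelist(ig)
  if (!nrow(el)) return(NULL)
  dddnet:::graph_from_edges(sprintf("v%02d", el[, 1]), sprintf("v%02d", el[, 2]))
}
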