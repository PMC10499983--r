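Package: dddnet
Title: Dominating David Derived Networks and Exact Degree-Based Topological Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Constructs honeycomb networks HC(t) and the family of dominating
    David derived networks (DDD(t) and its three derived types D1(t), D2(t),
    D3(t)) by an exact geometric pipeline on a rational lattice, extracts
    degree-pair edge partitions, and computes degree-based topological indices
    (forgotten index F*, second Zagreb index M2*, hyper-Zagreb index HM) with
    exact integer arithmetic, both edge-by-edge on a graph and from parametric
    edge-partition tables. Expands parametric partitions into closed-form
    quadratic polynomials in the dimension t, fits and certifies quadratics
    from brute-force counts, and audits the published closed forms for this
    family against the exact expansions, reporting every coefficient-level
    discrepancy rather than silently correcting either side.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
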