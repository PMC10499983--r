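test_that("exact expansion reproduces the hand-derived closed forms", {
  tabs <- ddd_partition_tables()
  for (fam in names(derived_forms)) {
    for (ix in names(derived_forms[[fam]])) {
      got <- expand_index(tabs[[fam]], ix)
      expect_identical(unname(unclass(got)), derived_forms[[fam]][[ix]],
                       info = paste(fam, ix))
    }
  }
})

test_that("expansion and evaluation commute", {
  tabs <- ddd_partition_tables()
  for (fam in names(tabs)) {
    for (ix in c("fn", "m2", "hm")) {
      poly <- expand_index(tabs[[fam]], ix)
      for (t in 1:10) {
        expect_identical(qp_eval(poly, t),
                         index_from_partition(evaluate_parametric(tabs[[fam]], t), ix))
      }
    }
  }
})

test_that("quadratic fitting recovers the expansion from table-generated counts", {
  tabs <- ddd_partition_tables()
  for (fam in names(tabs)) {
    for (ix in c("fn", "m2", "hm")) {
      counts <- vapply(1:5, function(t) {
        index_from_partition(evaluate_parametric(tabs[[fam]], t), ix)
      }, numeric(1))
      fit <- fit_quadratic_counts(counts, 1:5)
      expect_true(fit$certified)
      expect_identical(unclass(fit$poly), unclass(expand_index(tabs[[fam]], ix)))
    }
  }
})

test_that("fitting certifies constants and rejects cubic growth", {
  f_const <- fit_quadratic_counts(c(5, 5, 5, 5), 1:4)
  expect_true(f_const$certified)
  expect_identical(unname(unclass(f_const$poly)), c(0, 0, 5))
  f_cubic <- fit_quadratic_counts((1:4)^3, 1:4)
  expect_false(f_cubic$certified)
  expect_error(fit_quadratic_counts(c(1, 2, 3), 1:3), "at least 4")
})

test_that("fitting accepts a graph builder with an index", {
  fit <- fit_quadratic_counts(function(t) derive_type3(build_ddd(t)), 1:4, index = "hm")
  expect_true(fit$certified)
  expect_identical(unname(unclass(fit$poly)), c(5904, -7568, 2816))
})

test_that("the printed registry stores the published coefficients verbatim", {
  pr <- printed_closed_forms()
  pick <- function(fam, ix) unlist(pr[pr$family == fam & pr$index == ix, c("c2", "c1", "c0")])
  expect_identical(unname(pick("d2", "FN_STAR")), c(2286, -2758, 998))
  expect_identical(unname(pick("d1", "FN_STAR")), c(2214, -1951, 958))
  expect_identical(unname(pick("d2", "HM_N")), c(4518, -5055, 2030))
  m2d3 <- pr[pr$family == "d3" & pr$index == "M2_STAR", ]
  expect_identical(m2d3$printed, "1440t^2 - 1872 + 704")
  expect_match(m2d3$note, "lacks its factor t")
})

test_that("the audit flags exactly the three inconsistent published polynomials", {
  a <- audit_closed_forms()
  expect_identical(nrow(a), 9L)
  bad <- a[!a$match, c("family", "index")]
  expect_setequal(paste(bad$family, bad$index),
                  c("d1 FN_STAR", "d1 HM_N", "d2 HM_N"))
  # deltas localised as derived by hand: linear term for (d1, FN) and
  # (d2, HM); linear and constant terms for (d1, HM)
  row <- function(fam, ix) a[a$family == fam & a$index == ix, ]
  expect_identical(unname(unlist(row("d1", "FN_STAR")[, c("delta_c2", "delta_c1", "delta_c0")])),
                   c(0, 703, 0))
  expect_true(row("d1", "HM_N")$delta_c1 != 0 && row("d1", "HM_N")$delta_c0 != 0)
  expect_true(row("d2", "HM_N")$delta_c1 != 0 && row("d2", "HM_N")$delta_c0 == 0)
})

test_that("audited derived coefficients are confirmed by the brute-force oracle", {
  # independent route: evaluate partitions at t = 1..4, interpolate, certify
  tabs <- ddd_partition_tables()
  a <- audit_closed_forms()
  for (i in seq_len(nrow(a))) {
    counts <- vapply(1:4, function(t) {
      index_from_partition(evaluate_parametric(tabs[[a$family[i]]], t), a$index[i])
    }, numeric(1))
    fit <- fit_quadratic_counts(counts, 1:4)
    expect_true(fit$certified)
    expect_identical(unname(unclass(fit$poly)),
                     c(a$derived_c2[i], a$derived_c1[i], a$derived_c0[i]))
  }
})
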