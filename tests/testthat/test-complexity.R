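worked_tt <- function() expr_to_tt(parse_expr("~x1~x2~x3 + ~x1~x2x3 + ~x1x2~x3"), 3)

test_that("average sensitivity and edge counts obey the kP identity", {
  expect_equal(average_sensitivity(truth_table(c(0, 1, 1, 0))), 2)
  expect_equal(average_sensitivity(truth_table(c(0, 0, 0, 1))), 1)
  expect_equal(average_sensitivity(worked_tt()), 1.25)

  expect_equal(hypercube_edges(truth_table(c(0, 0, 0, 1))),
               c(E01 = 2L, E11 = 0L))
  expect_equal(hypercube_edges(truth_table(rep(1, 8))),
               c(E01 = 0L, E11 = 12L))

  set.seed(17)
  for (rep in 1:25) {
    k <- sample(2:4, 1)
    tt <- rand_tt(k)
    ed <- hypercube_edges(tt)
    expect_equal(ed, oracle_edges(tt))
    expect_equal(unname(ed["E01"] + 2L * ed["E11"]), k * bias(tt))
    expect_equal(average_sensitivity(tt), oracle_sensitivity(tt))
    expect_equal(average_sensitivity(tt), 2 * unname(ed["E01"]) / 2^k)
  }
})

test_that("sensitivity is invariant under isomorphism and complementation", {
  set.seed(19)
  for (rep in 1:10) {
    tt <- rand_tt(4)
    s <- average_sensitivity(tt)
    expect_equal(average_sensitivity(tt_complement(tt)), s)
    expect_equal(average_sensitivity(canonical_form(tt)), s)
  }
})

test_that("Quine-McCluskey finds the exact minimal two-level forms", {
  qd <- qm_minimize(worked_tt(), "DNF")
  expect_equal(expr_literal_count(qd), 4)          # ~x1~x2 + ~x1~x3
  expect_equal(expr_to_tt(qd, 3)$outputs, worked_tt()$outputs)

  single <- truth_table(c(0, 0, 0, 1))
  qs <- qm_minimize(single, "DNF")
  expect_equal(expr_literal_count(qs), 2)
  expect_error(qm_minimize(truth_table(rep(0, 4))), "constant")

  set.seed(23)
  for (rep in 1:15) {
    tt <- rand_tt(4)
    if (bias(tt) %in% c(0, 16)) next
    for (target in c("DNF", "CNF")) {
      e <- qm_minimize(tt, target)
      expect_equal(expr_to_tt(e, 4)$outputs, tt$outputs)
    }
  }
})

test_that("factoring recovers the 3-literal form and never grows the count", {
  f <- factorize_expr(qm_minimize(worked_tt(), "DNF"))
  expect_equal(expr_literal_count(f), 3)
  expect_equal(expr_to_tt(f, 3)$outputs, worked_tt()$outputs)

  single <- parse_expr("~x2")
  expect_equal(format_expr(factorize_expr(single)), "~x2")

  set.seed(29)
  for (rep in 1:15) {
    tt <- rand_tt(4)
    if (bias(tt) %in% c(0, 16)) next
    e <- qm_minimize(tt, "DNF")
    f <- factorize_expr(e)
    expect_lte(expr_literal_count(f), expr_literal_count(e))
    expect_equal(expr_to_tt(f, 4)$outputs, tt$outputs)
  }
})

test_that("boolean_complexity takes the best of the four seeds", {
  rec <- boolean_complexity(worked_tt())
  expect_equal(rec$boolean_complexity, 3)
  expect_equal(rec$average_sensitivity, 1.25)
  expect_equal(rec$E01, 5)
  expect_equal(rec$E11, 2)
  expect_false(rec$exact)

  expect_equal(boolean_complexity(truth_table(c(0, 1, 1, 0)))$boolean_complexity, 4)
  expect_equal(boolean_complexity(truth_table(rep(0, 4)))$boolean_complexity, 0)

  # every NCF has a k-literal formula; the estimate must find it
  for (k in 2:4) {
    keys <- build_catalog(k, "NCF")$keys
    some <- if (length(keys) > 40) sample(keys, 40) else keys
    for (kk in some) {
      expect_equal(boolean_complexity(hex_to_tt(kk, k))$boolean_complexity, k)
    }
  }
})

test_that("exact search certifies minimal literal counts at small k", {
  expect_equal(boolean_complexity_exact(worked_tt()), 3)
  expect_equal(boolean_complexity_exact(truth_table(c(0, 1, 1, 0))), 4)
  expect_error(boolean_complexity_exact(truth_table(rep(1, 4))), "constant")

  # the exact value is a lower bound on the heuristic estimate (k = 3, all)
  for (id in 1:254) {
    tt <- truth_table(bitwAnd(bitwShiftR(id, 0:7), 1L), 3)
    ex <- boolean_complexity_exact(tt)
    expect_lte(ex, boolean_complexity(tt)$boolean_complexity)
    if (is_effective(tt)) expect_gte(ex, 3)
  }
  # effective functions need at least k literals; RoFs attain exactly k
  expect_equal(boolean_complexity_exact(expr_to_tt(parse_expr("x1x2(x3+x4)"), 4)), 4)
})
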