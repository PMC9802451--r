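test_that("bias counts ones and complement mirrors it", {
  worked <- expr_to_tt(parse_expr("~x1~x2~x3 + ~x1~x2x3 + ~x1x2~x3"), 3)
  expect_equal(bias(worked), 3)
  expect_equal(bias(truth_table(rep(0, 4))), 0)
  expect_equal(bias(truth_table(c(0, 1, 1, 0))), 2)

  and2 <- truth_table(c(0, 0, 0, 1))
  expect_equal(bias(tt_complement(and2)), 3)
  set.seed(11)
  for (rep in 1:20) {
    tt <- rand_tt(4)
    expect_equal(bias(tt) + bias(tt_complement(tt)), 16)
    expect_true(tt_complement(tt_complement(tt)) == tt)
    expect_equal(average_sensitivity(tt_complement(tt)), average_sensitivity(tt))
  }
})

test_that("truth-table string and hex serialisation round-trips", {
  tt <- truth_table(c(0, 1, 1, 1, 0, 0, 1, 0))
  expect_equal(as_truth_table(tt_to_string(tt))$outputs, tt$outputs)
  expect_equal(as_truth_table(tt_to_string(tt, "lsb"), bit_order = "lsb")$outputs,
               tt$outputs)
  expect_equal(hex_to_tt(tt_to_hex(tt), 3)$outputs, tt$outputs)
  set.seed(5)
  for (k in c(1, 2, 5)) {
    tt <- rand_tt(k)
    expect_equal(hex_to_tt(tt_to_hex(tt), k)$outputs, tt$outputs)
  }
  expect_error(truth_table(c(0, 1, 2, 0)), "0 or 1")
  expect_error(truth_table(c(0, 1, 1)), "2\\^k")
})

test_that("expression parsing handles the published grammar", {
  e <- parse_expr("x1 & (x2 | x3)")
  expect_equal(e$op, "and")
  expect_equal(expr_literal_count(e), 3)

  minimal <- parse_expr("~x1 & (~x2 | ~x3)")
  expect_equal(expr_literal_count(minimal), 3)
  tt <- expr_to_tt(minimal, 3)
  expect_equal(which(tt$outputs == 1) - 1, c(0, 2, 4))
  expect_equal(bias(tt), 3)

  expect_equal(expr_to_tt(parse_expr("x1"), 1)$outputs, c(0L, 1L))
  # juxtaposition AND and + OR
  t1 <- expr_to_tt(parse_expr("x1x2(x3+x4)"), 4)
  t2 <- expr_to_tt(parse_expr("x1(x2x3+x4)"), 4)
  expect_false(all(t1$outputs == t2$outputs))

  expect_error(parse_expr("x1 &"), "syntax error")
  expect_error(parse_expr("x1 | (x2"), "expected ')'")
  expect_error(expr_to_tt(parse_expr("x5"), 3), "exceeds k")
})

test_that("negation is pushed to literals (NNF) and format round-trips", {
  e <- parse_expr("~(x1 & ~(x2 | x3))")
  count_nonlit_neg <- function(x) {
    if (x$op == "lit") return(0L)
    sum(vapply(x$args, count_nonlit_neg, integer(1)))
  }
  expect_equal(count_nonlit_neg(e), 0L)
  set.seed(42)
  exprs <- c("~(x1x2 + ~x3(x1 | ~x2))", "x1 | ~(x2 & (x3 | ~x1))",
             "~~x1 & x2", "(x1 + x2)(~x3 + x1)")
  for (s in exprs) {
    e <- parse_expr(s)
    k <- expr_max_var(e)
    expect_equal(expr_to_tt(parse_expr(format_expr(e)), k)$outputs,
                 expr_to_tt(e, k)$outputs)
  }
})

test_that("canonical form identifies isomorphic functions", {
  f <- expr_to_tt(parse_expr("x1 & (x2 | x3)"), 3)
  g <- expr_to_tt(parse_expr("x2 & (x1 | ~x3)"), 3)
  expect_equal(canonical_form(f)$outputs, canonical_form(g)$outputs)

  const <- truth_table(rep(1, 8))
  expect_equal(canonical_form(const)$outputs, const$outputs)

  set.seed(7)
  for (rep in 1:5) {
    tt <- rand_tt(3)
    cf <- canonical_form(tt)
    expect_equal(cf$outputs, oracle_canonical(tt)$outputs)
    expect_equal(canonical_form(cf)$outputs, cf$outputs)  # idempotent
  }
  # constant on orbits: random transforms preserve the canonical form
  set.seed(8)
  for (rep in 1:5) {
    tt <- rand_tt(4)
    p <- sample(4)
    neg <- sample(0:15, 1)
    m <- 0:15
    out <- integer(16)
    for (mm in m) {
      x <- bitwAnd(bitwShiftR(mm, 0:3), 1L)
      y <- bitwXor(x[p], bitwAnd(bitwShiftR(neg, 0:3), 1L))
      out[mm + 1] <- tt$outputs[sum(y * 2^(0:3)) + 1]
    }
    expect_equal(canonical_form(truth_table(out, 4))$outputs,
                 canonical_form(tt)$outputs)
  }
})
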