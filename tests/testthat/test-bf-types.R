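test_that("effective inputs are detected and ineffective ones truncated", {
  proj1 <- truth_table(c(0, 1, 0, 1))          # f(x1,x2) = x1
  expect_equal(effective_inputs(proj1), 1L)
  expect_false(is_effective(proj1))
  tr <- truncate_ineffective(proj1)
  expect_equal(tr$tt$outputs, c(0L, 1L))
  expect_equal(tr$kept, 1L)

  xor2 <- truth_table(c(0, 1, 1, 0))
  expect_true(is_effective(xor2))
  expect_equal(truncate_ineffective(xor2)$tt$outputs, xor2$outputs)

  expect_error(truncate_ineffective(truth_table(rep(0, 4))), "constant")

  # force input 3 ineffective in a random k=4 function by construction
  set.seed(21)
  for (rep in 1:10) {
    base <- rand_tt(3)
    while (!is_effective(base)) base <- rand_tt(3)
    out4 <- integer(16)
    for (m in 0:15) {
      src <- bitwAnd(m, 3L) + 4L * bitwAnd(bitwShiftR(m, 3L), 1L)
      out4[m + 1] <- base$outputs[src + 1]
    }
    tt4 <- truth_table(out4, 4)
    expect_equal(setdiff(1:4, effective_inputs(tt4)), 3L)
    tr <- truncate_ineffective(tt4)
    expect_equal(tr$tt$outputs, base$outputs)
  }
})

test_that("input signs and unateness follow the monotonicity conditions", {
  worked <- expr_to_tt(parse_expr("~x1(~x2 + ~x3)"), 3)
  expect_equal(input_signs(worked), rep("inhibiting", 3))
  expect_true(is_unate(worked))

  xor2 <- truth_table(c(0, 1, 1, 0))
  expect_equal(input_signs(xor2), rep("mixed", 2))
  expect_false(is_unate(xor2))

  # an input that is both activating and inhibiting is ineffective
  # (exhaustive over all k=3 functions)
  for (id in 0:255) {
    tt <- truth_table(bitwAnd(bitwShiftR(id, 0:7), 1L), 3)
    signs <- input_signs(tt)
    both <- which(signs == "both")
    expect_equal(both, setdiff(1:3, effective_inputs(tt)))
  }
})

test_that("canalyzing inputs list (i, a, b) triples forcing the output", {
  and2 <- truth_table(c(0, 0, 0, 1))
  can <- canalyzing_inputs(and2)
  expect_equal(can$input, c(1L, 2L))
  expect_equal(can$value, c(0L, 0L))
  expect_equal(can$output, c(0L, 0L))
  expect_true(is_canalyzing(and2))
  expect_equal(nrow(canalyzing_inputs(truth_table(c(0, 1, 1, 0)))), 0L)
  # constants are canalyzing in every input and value
  expect_true(is_canalyzing(truth_table(rep(1, 4))))
})

test_that("nested canalyzing recognition matches the chain definition", {
  e <- parse_expr("x1 & (~x2 | x3)")
  expect_true(is_ncf(expr_to_tt(e, 3)))
  maj3 <- truth_table(as.integer(sapply(0:7, function(m) {
    sum(bitwAnd(bitwShiftR(m, 0:2), 1L)) >= 2
  })), 3)
  expect_false(is_ncf(maj3))
  res <- is_ncf(expr_to_tt(e, 3), witness = TRUE)
  chain <- attr(res, "chain")
  expect_equal(nrow(chain), 3L)
  expect_equal(chain$input[1], 1L)  # x1 = 0 canalyzes first

  # agreement with the direct nested-chain enumeration for k <= 4
  for (k in 1:4) {
    keys <- oracle_ncf_keys(k)
    expect_equal(sort(build_catalog(k, "NCF")$keys), keys)
    ids <- if (k <= 3) 0:(2^(2^k) - 1) else NULL
    if (!is.null(ids)) {
      flags <- vapply(ids, function(id) {
        is_ncf(truth_table(bitwAnd(bitwShiftR(id, 0:(2^k - 1)), 1L), k))
      }, logical(1))
      member <- vapply(ids, function(id) {
        tt_to_hex(truth_table(bitwAnd(bitwShiftR(id, 0:(2^k - 1)), 1L), k)) %in% keys
      }, logical(1))
      expect_equal(flags, member)
    }
  }
})

test_that("catalog counts and containments match the known census", {
  ncf_counts <- c(2, 8, 64, 736, 10624)
  rof_counts <- c(2, 8, 64, 832, 15104)
  for (k in 1:5) {
    expect_equal(build_catalog(k, "NCF")$count, ncf_counts[k])
    expect_equal(build_catalog(k, "RoF")$count, rof_counts[k])
  }
  expect_equal(build_catalog(4, "nonNCF-RoF")$count, 96)
  # NCFs are a subset of RoFs, strict from k = 4
  for (k in 1:4) {
    expect_true(all(build_catalog(k, "NCF")$keys %in% build_catalog(k, "RoF")$keys))
  }
  expect_lt(build_catalog(4, "NCF")$count, build_catalog(4, "RoF")$count)
  # every RoF with bias 1, 3 or 5 is an NCF (k <= 5)
  for (k in 4:5) {
    rof <- build_catalog(k, "RoF")
    ncf_keys <- build_catalog(k, "NCF")$keys
    low_bias <- vapply(rof$keys, function(kk) {
      bias(hex_to_tt(kk, k)) %in% c(1, 3, 5)
    }, logical(1))
    expect_true(all(rof$keys[low_bias] %in% ncf_keys))
  }
})

test_that("is_rof resolves membership and rejects oversized k", {
  expect_true(is_rof(expr_to_tt(parse_expr("x1x2(x3 + x4)"), 4)))
  parity4 <- truth_table(as.integer(sapply(0:15, function(m) {
    sum(bitwAnd(bitwShiftR(m, 0:3), 1L)) %% 2
  })), 4)
  expect_false(is_rof(parity4))
  expect_error(is_rof(truth_table(rep(c(0, 1), 64), 7)), "catalog bound")
  # all RoFs have odd bias (k = 4 catalog scan)
  biases <- vapply(build_catalog(4, "RoF")$keys,
                   function(kk) bias(hex_to_tt(kk, 4)), numeric(1))
  expect_true(all(biases %% 2 == 1))
})

test_that("classify_bf populates a consistent profile", {
  p_and <- classify_bf(truth_table(c(0, 0, 0, 1)))
  expect_true(p_and$is_effective && p_and$is_unate && p_and$is_canalyzing &&
                p_and$is_ncf && p_and$is_rof)
  expect_equal(p_and$bias, 1L)
  expect_equal(p_and$parity, "odd")

  p_xor <- classify_bf(truth_table(c(0, 1, 1, 0)))
  expect_true(p_xor$is_effective)
  expect_false(p_xor$is_unate || p_xor$is_canalyzing || p_xor$is_ncf ||
                 p_xor$is_rof)
  expect_equal(p_xor$parity, "even")

  # invariant lattice on random functions: NCF => RoF => unate, effective, odd
  set.seed(33)
  pool <- c(lapply(1:30, function(i) rand_tt(3)),
            lapply(sample(build_catalog(4, "RoF")$keys, 25), hex_to_tt, k = 4))
  for (tt in pool) {
    p <- classify_bf(tt)
    if (p$is_ncf) expect_true(p$is_rof)
    if (isTRUE(p$is_rof)) {
      expect_true(p$is_effective && p$is_unate && p$parity == "odd")
    }
    if (!p$is_effective) expect_equal(p$parity, "even")
    expect_equal(p$is_effective, length(p$ineffective_inputs) == 0L)
  }
})
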