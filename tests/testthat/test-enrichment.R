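test_that("reference datasets round-trip through the TSV format", {
  ds <- make_tiny_dataset()
  expect_equal(nrow(ds), 10)
  expect_equal(unique(ds$k), 2L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rules_tsv(ds, path)
  back <- read_rules_tsv(path)
  expect_equal(back$output_bits, ds$output_bits)
  expect_equal(back$regulators, ds$regulators)
})

test_that("BoolNet expression files compile to truth tables", {
  path <- withr::local_tempfile(fileext = ".bn")
  writeLines(c("targets, factors",
               "A, B & !C",
               "B, A",
               "C, !(A | B) | C"), path)
  ds <- read_boolnet(path)
  expect_equal(ds$k, c(2L, 1L, 3L))
  a <- as_truth_table(ds$output_bits[ds$node_id == "A"], k = 2)
  expect_equal(a$outputs, expr_to_tt(parse_expr("x1 & ~x2"), 2)$outputs)
  expect_equal(ds$regulators[ds$node_id == "A"], "B,C")
  expect_error(read_boolnet(withr::local_tempfile(lines = "nope")),
               "targets, factors")
})

test_that("relative abundance counts type members per in-degree", {
  ds <- make_tiny_dataset()         # 5 AND2 + 5 XOR2
  expect_equal(relative_abundance(ds, "NCF", 2), 0.5)
  expect_equal(relative_abundance(ds, "odd", 2), 0.5)
  expect_equal(relative_abundance(ds, "EF", 2), 1)
  expect_error(relative_abundance(ds, "NCF", 3), "no rules")
})

test_that("enrichment test computes E = f1/f0 and an exact binomial tail", {
  ds <- make_tiny_dataset()
  res <- enrichment_test(ds, "NCF", 2)       # f0 = 8/16
  expect_equal(res$f0, 0.5)
  expect_equal(res$f1, 0.5)
  expect_equal(res$E, 1)
  expect_gt(res$p_value, 0.3)                # on-null is not significant

  # Table-1-style magnitudes
  res2 <- enrichment_test(ds, "NCF", 2, f0 = 1.12e-2)
  expect_equal(res2$E, 0.5 / 1.12e-2, tolerance = 1e-12)

  # all n rules of the type with tiny f0: tail is exactly f0^n
  ds_and <- ds[ds$output_bits == tt_to_string(truth_table(c(0, 0, 0, 1))), ]
  ds_and <- reference_dataset(as.data.frame(ds_and))
  res3 <- enrichment_test(ds_and, "NCF", 2, f0 = 1e-3)
  expect_equal(res3$p_value, 1e-3^5, tolerance = 1e-9)
  expect_error(enrichment_test(ds, "NCF", 2, f0 = 0), "between 0 and 1")
})

test_that("relative enrichment compares subtype shares against the null", {
  ds <- make_tiny_dataset()
  res <- relative_enrichment_test(ds, "NCF", "CF", 2)
  expect_equal(res$n, 5)                     # only the AND2 rules are CFs
  expect_equal(res$fs1_over_f1, 1)
  expect_equal(res$fs0_over_f0, 8 / 14)
  expect_equal(res$E_R, 14 / 8)
  # E_R equals E(subtype)/E(englobing type) when the subtype is contained
  e_sub <- enrichment_test(ds, "NCF", 2)
  e_typ <- enrichment_test(ds, "CF", 2)
  expect_equal(res$E_R, e_sub$E / e_typ$E, tolerance = 1e-12)
  expect_error(relative_enrichment_test(make_tiny_dataset(), "NCF", "UF", 3),
               "no rules")
})

test_that("p-values are calibrated (super-uniform) under the null", {
  set.seed(77)
  n <- 120
  f0 <- build_catalog(3, "NCF")$count / 256
  pvals <- replicate(150, {
    bits <- vapply(seq_len(n), function(i) {
      tt_to_string(truth_table(sample(0:1, 8, replace = TRUE)))
    }, character(1))
    ds <- reference_dataset(data.frame(
      model_id = "m", node_id = paste0("n", seq_len(n)),
      regulators = "a,b,c", output_bits = bits))
    enrichment_test(ds, "NCF", 3, f0)$p_value
  })
  for (alpha in c(0.01, 0.05, 0.1, 0.25)) {
    expect_lte(mean(pvals <= alpha), alpha + 3 * sqrt(alpha * (1 - alpha) / 150))
  }
})

test_that("truncated view replaces ineffective rules by reduced ones", {
  proj <- tt_to_string(truth_table(c(0, 1, 0, 1)))   # f(x1,x2) = x1
  and2 <- tt_to_string(truth_table(c(0, 0, 0, 1)))
  const <- tt_to_string(truth_table(rep(1, 4)))
  ds <- reference_dataset(data.frame(
    model_id = "m", node_id = c("a", "b", "c"),
    regulators = c("u,v", "u,v", "u,v"),
    output_bits = c(proj, and2, const)))
  expect_warning(tv <- truncated_view(ds), "constant")
  expect_equal(nrow(tv), 2)
  expect_equal(sort(tv$k), c(1L, 2L))
  expect_equal(tv$regulators[tv$node_id == "a"], "u")
  expect_equal(tv$output_bits[tv$node_id == "b"], and2)
})
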