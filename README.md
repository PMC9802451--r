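# boolrules

Tools for quantifying the *complexity of regulatory logic* in Boolean models
of biological networks.

In a Boolean network, each gene or protein is on/off and node *i* is updated
by a Boolean function f_i of its k_i regulators. Curated models do not use
random functions: their update rules are overwhelmingly drawn from a handful
of *biologically meaningful* types — effective functions (EF, every input
matters), unate functions (UF, each input consistently activating or
inhibiting), canalyzing functions (CF, some input value forces the output),
nested canalyzing functions (NCF, canalyzing recursively down to a single
literal), and read-once functions (RoF, expressible with every variable
appearing exactly once). `boolrules` implements classifiers, exact catalogs,
and census/enrichment statistics for all of these, together with the two
complexity measures that explain their prevalence:

* **Boolean complexity** — the number of literals in a function's shortest
  AND/OR/NOT formula. Estimated as the best of four factorized seeds (full
  DNF, full CNF, Quine–McCluskey minimal DNF/CNF, each passed through
  algebraic factoring), and computed *exactly* for k ≤ 4 by a dynamic
  program over formula cost. RoFs attain the minimum (k literals) among all
  effective k-input functions.
* **Average sensitivity** — S_f = ⟨Σ_i f(x ⊕ e_i) ⊕ f(x)⟩_x, the expected
  number of single-input flips that change the output. With E01 the number
  of hypercube edges joining differing outputs and E11 the edges joining two
  1-outputs, E01 + 2·E11 = k·P (P = bias, the number of 1 outputs) and
  S_f = 2·E01 / 2^k. Hart's edge-maximizing "good sets" realize the minimum
  of S_f at fixed bias; for odd P the minimizer is an NCF, for even P it is
  an ineffective function.

The package also samples type-constrained random rules onto fixed network
wirings to study the *network average sensitivity* s (mean node sensitivity;
s ≈ 1 is the critical regime), generates reproducible synthetic model
collections that emulate curated datasets, and reads/writes rules as TSV
tables or BoolNet-style expression files.

## Worked example

The 3-input function given by its full DNF with 9 literals,
f = x̄1·x̄2·x̄3 + x̄1·x̄2·x3 + x̄1·x2·x̄3, reduces to the 3-literal formula
x̄1·(x̄2 + x̄3):

```r
library(boolrules)
tt <- expr_to_tt(parse_expr("~x1~x2~x3 + ~x1~x2x3 + ~x1x2~x3"), 3)

qm <- qm_minimize(tt, "DNF")
format_expr(qm)               # "~x1 & ~x3 | ~x1 & ~x2"   (4 literals)
boolean_complexity(tt)
#> complexity_record: k=3 P=3 | literals=3 (qm_dnf) | S=1.25 E01=5 E11=2
#>   expr: ~x1 & (~x3 | ~x2)
boolean_complexity_exact(tt)  # 3  (certified by exhaustive search)

classify_bf(tt)
#> type_profile: k=3 P=3 (odd) | EF=yes UF=yes CF=yes NCF=yes RoF=yes
#>   input signs: inhibiting, inhibiting, inhibiting
```

The two-level minimum needs 4 literals; factoring recovers the 3-literal
formula, which equals the exact minimum. The function is nested canalyzing,
and its average sensitivity 1.25 (= 2·5/8) is the smallest possible for any
3-input function with bias 3:

```r
min_average_sensitivity(3, 3)          # 1.25
format_expr(good_set_to_ncf(good_set(4, 13)))
#> "~x4 | ~x3 | x2 & x1"                # the bias-13 minimizer on the 4-cube
```

Catalogs and censuses over the whole function space:

```r
catalog_census(4)
#> census_table: k = 4, 65,536 functions
#>        type count fraction  odd even
#>         RoF   832  1.27e-02  832    0
#>  nonNCF-RoF    96  1.46e-03   96    0
#>         NCF   736  1.12e-02  736    0
subtype_fraction(4, "NCF", "CF")       # 0.2094479
```

A command-line front end is installed at `inst/cli/boolrules`
(`boolrules classify --tt 0001`, `boolrules goodset 4 13`,
`boolrules census --k 4`, `boolrules fixtures --out dir --seed 1`, ...).

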