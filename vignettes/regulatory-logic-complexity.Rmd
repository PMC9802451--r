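---
title: "Complexity measures for Boolean regulatory logic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity measures for Boolean regulatory logic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boolrules)
```

## The setting

A Boolean network model represents each gene or protein as an on/off
variable $x_i$ and updates node $i$ with a Boolean function $f_i$ of its
$k_i$ regulators. `boolrules` is about the *update rules themselves*: which
functions appear in curated models, how to classify them, and how to
quantify their simplicity. Two complexity measures organize everything:

**Boolean complexity** $L(f)$ is the number of literals in the shortest
AND/OR/NOT formula for $f$. It is representation-based: the 3-input function
with full disjunctive normal form
$\bar x_1\bar x_2\bar x_3 + \bar x_1\bar x_2 x_3 + \bar x_1 x_2\bar x_3$
(9 literals) has $L(f)=3$ because it equals $\bar x_1(\bar x_2+\bar x_3)$.

**Average sensitivity** $S_f$ is distribution-based: the expected number of
single-input flips that change the output, uniformly over the $2^k$ input
assignments,
$$S_f \;=\; \Big\langle \sum_{i=1}^k f(\mathbf x\oplus\mathbf e_i)\oplus
f(\mathbf x)\Big\rangle_{\mathbf x}
\;=\; \frac{2\,E_{01}}{2^k},$$
where $E_{01}$ counts $k$-cube edges whose endpoints have differing
outputs. With $E_{11}$ the number of edges joining two 1-outputs and $P$
the bias (number of 1 outputs), $E_{01} + 2E_{11} = kP$, so minimizing
sensitivity at fixed bias is the same as maximizing $E_{11}$. We report
$S_f$ unnormalised, on $[0, k]$, because $s \approx 1$ is the critical
point of network dynamics.

## Function types and their classifiers

All classifiers act on a `truth_table`: $2^k$ output bits indexed so that
$x_1$ is the least-significant bit of the row index (serialisations print
rows most-significant-first; a `bit_order = "lsb"` dialect is accepted).

* **Effective** (`is_effective`): every input changes the output somewhere.
  An input that never matters should not be modelled as a regulator.
  Ineffective functions necessarily have even bias.
* **Unate** (`is_unate`): each input is monotone activating or inhibiting.
  An input that is simultaneously both is ineffective; an input that is
  neither is "mixed" and destroys unateness (e.g. XOR).
* **Canalyzing** (`is_canalyzing`): some input value forces the output
  regardless of the rest. We classify constants as canalyzing — the
  defining condition holds for them at every input — which keeps the
  canalyzing census consistent with the conditional abundances the package
  reports (e.g. the 2-input census counts 14 CFs: everything but XOR and
  XNOR).
* **Nested canalyzing** (`is_ncf`): canalyzing recursively, bottoming out
  at a single literal; equivalently a right-nested chain
  $X_{\sigma(1)}\odot(X_{\sigma(2)}\odot(\cdots X_{\sigma(k)}))$ of signed
  literals with $\odot\in\{\wedge,\vee\}$. The recognizer returns the first
  witness chain under ascending input index, canalyzing value 0 before 1.
* **Read-once** (`is_rof`): representable with every variable appearing
  exactly once. RoFs are effective, unate, odd-biased, and attain the
  minimum Boolean complexity $L(f)=k$ among effective functions; NCFs are
  exactly the RoFs with fully nested parenthesisation, a strict subset from
  $k = 4$.

### Catalogs

`build_catalog(k, type)` materialises the complete NCF/RoF truth-table sets
for $k \le 6$ by recursion over variable subsets with deduplication at each
level: an NCF on a set $S$ is a signed literal combined with an NCF on
$S\setminus\{i\}$; a RoF on $S$ is $g \odot h$ over a disjoint bipartition
of $S$. This generates exactly the sets defined by the chain and pairing
definitions but avoids enumerating the $k!\,2^{2k-1}$ raw expressions; the
equivalence is tested against direct chain enumeration at small $k$. The
counts are 2, 8, 64, 736, 10624, 183936 (NCF) and 2, 8, 64, 832, 15104,
352256 (RoF) for $k = 1..6$; both sequences are cross-checked in the test
suite against independent derivations (direct enumeration, the
series-parallel structure of read-once formulas). Read-once membership is a
direct lookup in the full catalog, so no canonicalization is involved.

`canonical_form()` provides input-isomorphism canonicalization (permuting
and negating inputs; output complementation is deliberately *not* part of
the orbit): the lexicographically smallest serialised output vector over
all $k!\,2^k$ transforms, exhaustive and therefore limited to $k \le 6$.

## Computing Boolean complexity

Minimal-formula search is intractable in general, so `boolean_complexity()`
reports a deterministic upper bound: the best of four seeds — full DNF,
full CNF, Quine–McCluskey minimal DNF, Quine–McCluskey minimal CNF — each
passed through algebraic factoring.

* The QM step computes all prime implicants by iterated merging and picks
  an exact minimum cover (branch and bound with essential-implicant
  reduction), minimising term count, then literal count, then a
  lexicographic key on the implicant masks so that results are
  reproducible. The CNF route minimises the complement and applies
  De Morgan.
* Factoring repeatedly divides out the most frequent literal (ties: lowest
  variable index, positive before negative) and recurses on quotient and
  remainder; absorption ($\ell + \ell q = \ell$) is applied, but no
  Boolean-law simplification beyond it, so the factoring is purely
  algebraic. Literal counts never increase.
* `boolean_complexity_exact()` certifies the true minimum for $k \le 4$ by
  dynamic programming over formula cost: cost-1 functions are the $2k$
  literals and every cost-$s$ function is $g\wedge h$ or $g\vee h$ with
  costs summing to $s$. The state space is the full $2^{2^k}$ function
  space packed into integers; levels are grown lazily and cached. Running
  it to exhaustion at $k=4$ shows every non-constant function is realised
  by cost 16 (4-input parity being the worst case), which also certifies
  that every catalogued NCF has exact complexity $k$ — an acceptance
  property of the test suite.

Constants are assigned complexity 0 and flagged; they have no literal
formula in this algebra.

## Good sets: sensitivity minimisers at fixed bias

Writing $P=\sum_i 2^{r_i}$, the good-set construction fills nested
subcubes: scanning the binary digits of $P$ from the most significant, each
1-digit fills the whole subcube on the side where the current splitting
coordinate is 0, and the recursion continues on the sibling subcube. All
choices are fixed (split on the highest free coordinate, fill the 0 side,
base-case vertex all-ones) so tests are deterministic; any other choice
gives an isomorphic function. The induced indicator function maximises
$E_{11}$ — verified exhaustively for every $(k \le 4, P)$ against the
full-space scan — and therefore minimises $S_f$ in its $k[P]$ set.

For odd $P$ the digit scan reads off a nested chain directly
(`good_set_to_ncf`): digit 1 contributes $\bar x\,\vee$, digit 0
contributes $x\,\wedge$, ending in a positive literal; e.g. $P=13$ on the
4-cube gives $\bar x_4 \vee (\bar x_3 \vee (x_2 \wedge x_1))$. For even
$P$ the chain stops at the last 1-digit, the remaining low coordinates are
ineffective, and `reduce_even_good_set` returns the NCF on the effective
variables — so bias-parity cleanly separates the two kinds of sensitivity
minimisers (NCFs vs ineffective functions).

## Census, enrichment, and the null model

`enumerate_census(k)` classifies the whole function space, vectorised over
all $2^{2^k}$ functions ($k\le4$; the $2^{32}$ functions at $k=5$ are out
of reach of a plain scan, and every $k=5$ quantity the package reports
comes from catalogs instead). `catalog_census(k)` covers RoF/NCF fractions
to $k = 6$; counts are exact integers below $2^{53}$ and the denominator
$2^{2^k}$ is an exact double, so even $10^{-14}$-scale fractions carry full
precision. The closed form
$\sum_j (-1)^j \binom{k}{j} 2^{2^{k-j}}$ for the effective count serves as
an independent oracle for the scan.

Enrichment statistics compare a rule collection against the uniform
ensemble: $E = f_1/f_0$ and, for a subtype inside an englobing type,
$E_R = (f_{s,1}/f_1)/(f_{s,0}/f_0)$. Significance is an exact one-sided
binomial tail — the natural test for "drawn uniformly from all functions",
adopted as the package's convention; no multiple-testing correction is
applied. Calibration
(super-uniform p-values under the simulated null) is asserted in the test
suite. Rules whose read-once status is undecidable ($k$ above the catalog
bound) are counted as non-members with a message.

## The synthetic model generator

`generate_collection()` emulates the *shape* of curated model collections,
not any particular dataset: 20 models of 8–15 nodes by default, in-degrees
geometrically decaying ($\Pr[k] \propto 2^{-k}$ up to $k_{\max} = 6$ —
rules with one or two inputs dominate, large in-degrees are rare), and a
rule-type mixture of 85% NCF, 5% RoF, 5% EF, 5% uniform-random, reflecting
the strong dominance of nested canalyzing logic in published models. Rules
are drawn uniformly within their type (catalog indexing for NCF/RoF,
exact-uniform rejection otherwise), and generation is bit-for-bit
reproducible from the seed. What the generator does *not* emulate: real
wiring topology (regulators are sampled uniformly), correlations between a
node's in-degree and its rule type, dataset-specific bias histograms, and
curation artefacts such as duplicated subnetworks. Tests passing on these
fixtures therefore validate the machinery, not any biological claim about
real model collections.

`type_sensitivity_distribution()` re-wires nothing: it keeps each model's
in-degree list and resamples rules by type, collecting network average
sensitivities (100 replicates per model by default — a package convention).
On the default fixture suite the NCF and RoF ensembles produce visibly
narrower distributions centred nearer $s=1$ than the EF ensemble, which the
acceptance tests assert with seeded draws. `ci_overlap()` quantifies
distribution separation as the mass outside a reference 95% interval
(percentiles by linear interpolation between order statistics).

## Numerical and design choices

* Row-index convention: $x_1$ is the least-significant bit; printed strings
  read $x_k..x_1$. Hex keys pack the same MSB-first order.
* Catalog-backed `is_rof` instead of a recursive disjoint-decomposition
  test: exact and cheap for $k\le6$; the bound is configurable but
  untested beyond 6.
* `boolean_complexity` ties between seeds resolve to the first in the
  order full DNF, full CNF, QM-DNF, QM-CNF.
* The exact-search budget defaults to 16 literals; the DP streams candidate
  pairs in chunks so memory stays bounded even when run to exhaustion.
* Rejection sampling caps at $10^6$ attempts and then errors with guidance,
  rather than hanging on types that are vanishingly rare at large $k$.
* Degenerate inputs: $k=0$ is unsupported; constants are admitted as truth
  tables, excluded from EF/NCF/RoF, included in CF, rejected by
  `truncate_ineffective` and by the minimal-formula searches.

## Known limitations

* Boolean-complexity estimates above $k=4$ are upper bounds; the four-seed
  heuristic can overshoot the true minimum for functions whose best
  formulas need factoring patterns beyond single-literal division.
* Any complexity *estimate* is representation-sensitive. For the
  complexity–sensitivity correlation at $k=4$ (computed by
  `scripts/acceptance.R` over all bias $\le 8$ functions, one minimisation
  per input-isomorphism class since both measures are class-invariant), the
  four-seed estimate and the exact formula minimum give
  $\rho \approx 0.87$–0.88. Estimates from multi-level logic-synthesis
  tools, which share subexpressions and so deflate the counts of
  high-sensitivity parity-like functions, yield lower correlations; with
  XOR admitted as a connective the exact-DP correlation drops to
  $\approx 0.45$. Comparisons of this statistic across toolchains should
  therefore fix the representation first.
* Full-space scans stop at $k=4$ and catalogs at $k=6$ by default; the
  structures beyond that are reachable only through the closed-form count
  and user-supplied `f0` values.
* The binomial enrichment test treats rules as independent draws; rules
  within one model are in reality curated together, so p-values on real
  collections are optimistic in scale, though the ratios $E$ and $E_R$ are
  unaffected.
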