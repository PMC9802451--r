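# ---- vectorized full-space scan -------------------------------------------

# 0/1 output matrix of every k-input function (row f = function id f, where
# bit m of f is the output at cube row m); feasible for k <= 4.
function_space_bits <- function(k) {
  n <- 2^(2^k)
  ids <- 0:(n - 1L)
  vapply(0:(2^k - 1L), function(r) bitwAnd(bitwShiftR(ids, r), 1L),
         integer(n))
}

# classify the whole k-input function space at once; cached per session
space_scan <- function(k) {
  if (k > 4L) stop("full-space scan supports k <= 4; use catalog_census()")
  key <- paste0("scan_", k)
  if (!is.null(.br_cache[[key]])) return(.br_cache[[key]])
  m <- function_space_bits(k)
  n <- nrow(m)
  eff <- act <- inh <- matrix(FALSE, n, k)
  canal <- rep(FALSE, n)
  e01 <- e11 <- integer(n)
  half <- 2^(k - 1L)
  for (i in seq_len(k)) {
    c0 <- rows_with_bit(k, i, 0L) + 1L
    lo <- m[, c0, drop = FALSE]
    hi <- m[, c0 + 2^(i - 1L), drop = FALSE]
    d <- lo != hi
    eff[, i] <- rowSums(d) > 0L
    e01 <- e01 + as.integer(rowSums(d))
    e11 <- e11 + as.integer(rowSums(lo * hi))
    act[, i] <- rowSums(lo > hi) == 0L
    inh[, i] <- rowSums(lo < hi) == 0L
    s0 <- rowSums(lo)
    s1 <- rowSums(m[, c0 + 2^(i - 1L), drop = FALSE])
    canal <- canal | s0 == 0L | s0 == half | s1 == 0L | s1 == half
  }
  keys <- pack_bits_hex(m)
  res <- data.frame(
    id = 0:(n - 1L),
    bias = as.integer(rowSums(m)),
    effective = rowSums(eff) == k,
    unate = rowSums(act | inh) == k,
    canalyzing = canal,
    ncf = keys %in% build_catalog(k, "NCF")$keys,
    rof = keys %in% build_catalog(k, "RoF")$keys,
    E01 = e01, E11 = e11,
    sensitivity = 2 * e01 / 2^k
  )
  .br_cache[[key]] <- res
  res
}

#' Census of biologically meaningful types over the full function space
#'
#' Classifies every one of the 2^(2^k) k-input functions and tabulates the
#' type counts: effective (EF), unate (UF), canalyzing (CF, constants
#' included), nested canalyzing (NCF), read-once (RoF), non-NCF RoF, and the
#' odd/even bias halves. Feasible for k <= 4; for larger k the RoF/NCF
#' columns are available through [catalog_census()].
#'
#' @param k number of inputs (1..4).
#' @return a `census_table`: data.frame with columns `type`, `count`,
#'   `fraction`, `odd`, `even` (parity cross-counts), with attributes `k`
#'   and `total`.
#' @export
enumerate_census <- function(k) {
  sc <- space_scan(k)
  n <- nrow(sc)
  odd <- sc$bias %% 2L == 1L
  cols <- list(EF = sc$effective, UF = sc$unate, CF = sc$canalyzing,
               RoF = sc$rof, `nonNCF-RoF` = sc$rof & !sc$ncf, NCF = sc$ncf,
               odd = odd, even = !odd)
  tab <- data.frame(
    type = names(cols),
    count = vapply(cols, sum, integer(1)),
    fraction = vapply(cols, function(x) sum(x) / n, numeric(1)),
    odd = vapply(cols, function(x) sum(x & odd), integer(1)),
    even = vapply(cols, function(x) sum(x & !odd), integer(1)),
    row.names = NULL
  )
  structure(tab, k = k, total = n, class = c("census_table", "data.frame"))
}

#' Catalog-based census (RoF / NCF / non-NCF RoF)
#'
#' Fractions of read-once and nested canalyzing functions in the space of
#' all 2^(2^k) functions, from the generated catalogs. Counts are exact
#' integers; the denominator 2^(2^k) is an exact power of two in double
#' precision, so the quotient is correct to ~15 significant digits even at
#' k = 6 where it is of order 1e-14.
#'
#' @param k number of inputs (1..6).
#' @return a `census_table` with rows RoF, nonNCF-RoF, NCF.
#' @export
catalog_census <- function(k) {
  if (k > 6L) stop("catalog census supports k <= 6")
  counts <- c(RoF = build_catalog(k, "RoF")$count,
              `nonNCF-RoF` = build_catalog(k, "nonNCF-RoF")$count,
              NCF = build_catalog(k, "NCF")$count)
  total <- 2^(2^k)
  tab <- data.frame(type = names(counts), count = unname(counts),
                    fraction = unname(counts) / total, odd = unname(counts),
                    even = 0L, row.names = NULL)
  structure(tab, k = k, total = total, class = c("census_table", "data.frame"))
}

#' @export
print.census_table <- function(x, ...) {
  cat(sprintf("census_table: k = %d, %s functions\n", attr(x, "k"),
              format(attr(x, "total"), big.mark = ",", scientific = FALSE)))
  df <- as.data.frame(x)
  df$fraction <- signif(df$fraction, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Closed-form count of effective functions
#'
#' Inclusion-exclusion over subsets of ignored inputs:
#' sum_j (-1)^j C(k, j) 2^(2^(k-j)). Exact for k <= 5 (all terms below
#' 2^53); for k = 6..10 the sum is evaluated in double precision, which
#' carries ~15 correct leading digits.
#'
#' @param k number of inputs (1..10).
#' @return the number of k-input functions in which every input is effective.
#' @export
count_effective_closed_form <- function(k) {
  if (k < 1L || k > 10L) stop("k must be in 1..10")
  j <- 0:k
  sum((-1)^j * choose(k, j) * 2^(2^(k - j)))
}

#' Subtype fraction within an englobing type, over the full space
#'
#' |subtype intersect type| / |type| among all 2^(2^k) functions, e.g. the
#' fraction of canalyzing functions that are nested canalyzing. The
#' NCF-in-RoF case uses the catalogs (k <= 6); every other pair needs the
#' full scan (k <= 4).
#'
#' @param k number of inputs.
#' @param subtype,within type labels among `"EF"`, `"UF"`, `"CF"`, `"NCF"`,
#'   `"RoF"`, `"nonNCF-RoF"`, `"odd"`, `"even"`.
#' @export
subtype_fraction <- function(k, subtype, within) {
  if (subtype == "NCF" && within == "RoF") {
    return(build_catalog(k, "NCF")$count / build_catalog(k, "RoF")$count)
  }
  sc <- space_scan(k)
  sel <- function(tp) {
    switch(tp,
           EF = sc$effective, UF = sc$unate, CF = sc$canalyzing,
           NCF = sc$ncf, RoF = sc$rof, `nonNCF-RoF` = sc$rof & !sc$ncf,
           odd = sc$bias %% 2L == 1L, even = sc$bias %% 2L == 0L,
           stop("unknown type '", tp, "'"))
  }
  den <- sel(within)
  if (!any(den)) stop("empty englobing type at k = ", k)
  sum(sel(subtype) & den) / sum(den)
}
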