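#' Hart's edge-maximizing good sets on the k-cube
#'
#' A good set places P vertices on the k-cube so that the number of edges
#' internal to the set (E11) is maximal. Construction: write
#' P = sum_i 2^(r_i) (strictly increasing exponents); scanning the binary
#' digits of P from the most significant, each 1-digit fills a whole subcube
#' of the corresponding dimension on the side where the current splitting
#' coordinate is 0, and the recursion continues on the sibling subcube. The
#' choices are fixed deterministically: the splitting coordinate is always
#' the highest free one, the filled side is coordinate = 0, and for odd P the
#' base-case vertex is the all-remaining-coordinates-1 vertex. The indicator
#' function of a good set attains the minimum average sensitivity in its
#' k[P] set; for odd P it is a nested canalyzing function, for even P it is
#' ineffective.
#'
#' @param k cube dimension (1..10).
#' @param P number of vertices, `1 <= P < 2^k`.
#' @return object of class `good_set`: list with `k`, `P`, `vertices`
#'   (0-based row indices), `dims` (exponents of the binary expansion of P),
#'   and `tt`, the induced [truth_table()].
#' @export
good_set <- function(k, P) {
  k <- as.integer(k)
  P <- as.integer(P)
  if (k < 1L || k > 10L) stop("k must be in 1..10")
  if (P < 1L || P >= 2^k) stop("P must satisfy 1 <= P < 2^k")
  b <- gs_digits(k, P)
  l <- max(which(b == 1L))
  m <- 0:(2^k - 1)
  out <- integer(2^k)
  undecided <- rep(TRUE, 2^k)
  for (i in seq_len(l)) {
    v <- bitwAnd(bitwShiftR(m, k - i), 1L)     # coordinate x_{k+1-i}
    if (i < l) {
      hit <- undecided & v == 0L
      out[hit] <- b[i]
      undecided <- undecided & v == 1L
    } else if (l < k) {
      out[undecided & v == 0L] <- 1L           # fill the final subcube
      out[undecided & v == 1L] <- 0L
    } else {
      out[undecided & v == 1L] <- 1L           # base vertex: all ones
      out[undecided & v == 0L] <- 0L
    }
  }
  tt <- truth_table(out, k)
  structure(list(k = k, P = P, vertices = which(out == 1L) - 1L,
                 dims = sort((k - seq_len(k))[b == 1L]), tt = tt),
            class = "good_set")
}

gs_digits <- function(k, P) {
  as.integer(bitwAnd(bitwShiftR(P, (k - 1L):0L), 1L))  # b_1 = MSB
}

#' @export
print.good_set <- function(x, ...) {
  cat(sprintf("good_set: k=%d P=%d, E11=%d, vertices: %s\n",
              x$k, x$P, unname(hypercube_edges(x$tt)["E11"]),
              paste(x$vertices, collapse = " ")))
  invisible(x)
}

#' Nested canalyzing expression of an odd good set
#'
#' For odd P the good set's indicator function is an NCF; this returns its
#' nested chain: scanning the binary digits b_1..b_k of P (MSB first), digit
#' i contributes `~x_(k+1-i) |` when b_i = 1 (that subcube is canalyzed to
#' output 1) and `x_(k+1-i) &` when b_i = 0 (canalyzed to 0), ending in the
#' positive literal x_1.
#'
#' @param gs a [good_set()] with odd P.
#' @return a `bool_expr` whose truth table equals `gs$tt`.
#' @export
good_set_to_ncf <- function(gs) {
  stopifnot(inherits(gs, "good_set"))
  if (gs$P %% 2L == 0L) {
    stop("even-P good set induces an ineffective reduced NCF; ",
         "use reduce_even_good_set()")
  }
  b <- gs_digits(gs$k, gs$P)
  e <- lit_(1L)
  if (gs$k > 1L) {
    for (i in (gs$k - 1L):1L) {
      v <- gs$k + 1L - i
      if (b[i] == 1L) e <- node_("or", list(lit_(v, TRUE), e))
      else e <- node_("and", list(lit_(v), e))
    }
  }
  e
}

#' Reduce an even good set to an NCF on fewer variables
#'
#' A good set with even P induces an ineffective function: the trailing zero
#' digits of P leave the lowest coordinates unused. The nested chain stops at
#' the last 1-digit (position l < k) with a negated final literal, giving an
#' NCF over the l highest-index variables; inputs x_1..x_(k-l) are
#' ineffective and the induced function's Boolean complexity is l < k.
#'
#' @param gs a [good_set()] with even P >= 2.
#' @return list with `expr` (a `bool_expr` in the original variable
#'   indices), `ineffective` (indices of the unused inputs), and `reduced`,
#'   the truncated [truth_table()] on the effective inputs.
#' @export
reduce_even_good_set <- function(gs) {
  stopifnot(inherits(gs, "good_set"))
  if (gs$P %% 2L == 1L) stop("P is odd; use good_set_to_ncf()")
  b <- gs_digits(gs$k, gs$P)
  l <- max(which(b == 1L))
  e <- lit_(gs$k + 1L - l, TRUE)
  if (l > 1L) {
    for (i in (l - 1L):1L) {
      v <- gs$k + 1L - i
      if (b[i] == 1L) e <- node_("or", list(lit_(v, TRUE), e))
      else e <- node_("and", list(lit_(v), e))
    }
  }
  list(expr = e,
       ineffective = seq_len(gs$k - l),
       reduced = truncate_ineffective(gs$tt)$tt)
}

#' Minimum average sensitivity in a k[P] set
#'
#' The sensitivity of the good-set-induced function, which attains the true
#' minimum over all bias-P functions (Hart's theorem); P and 2^k - P give
#' equal values by complementation.
#'
#' @param k number of inputs.
#' @param P bias, `0 <= P <= 2^k`.
#' @export
min_average_sensitivity <- function(k, P) {
  k <- as.integer(k)
  P <- as.integer(P)
  if (P < 0L || P > 2^k) stop("P must be in 0..2^k")
  if (P == 0L || P == 2^k) return(0)
  if (P > 2^(k - 1L)) P <- 2^k - P
  average_sensitivity(good_set(k, P)$tt)
}
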