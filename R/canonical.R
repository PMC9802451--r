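# Input-isomorphism canonicalization: two functions are isomorphic when one
# arises from the other by permuting and/or negating input variables (output
# complementation is NOT part of the orbit). The canonical form is the
# lexicographically smallest serialized output vector over all k! * 2^k
# transforms.

.br_cache <- new.env(parent = emptyenv())

all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- all_permutations(k - 1L)
    for (p in rest) {
      q <- seq_len(k)[-i]
      out[[length(out) + 1L]] <- c(i, q[p])
    }
  }
  out
}

# Matrix of 1-based source row indices, one row per transform: the transformed
# function's outputs are outputs[transform_row].
row_transforms <- function(k) {
  key <- paste0("transforms_", k)
  if (!is.null(.br_cache[[key]])) return(.br_cache[[key]])
  m <- 0:(2^k - 1)
  bits <- vapply(seq_len(k), function(i) bitwAnd(bitwShiftR(m, i - 1L), 1L),
                 integer(2^k))                       # 2^k x k
  perms <- all_permutations(k)
  pow <- 2^(0:(k - 1))
  res <- matrix(0L, nrow = length(perms) * 2^k, ncol = 2^k)
  r <- 1L
  for (p in perms) {
    xp <- bits[, p, drop = FALSE]                    # y_i before negation
    for (neg in 0:(2^k - 1)) {
      nu <- bitwAnd(bitwShiftR(neg, 0:(k - 1)), 1L)
      y <- xp
      flip <- which(nu == 1L)
      if (length(flip)) y[, flip] <- 1L - y[, flip, drop = FALSE]
      res[r, ] <- as.integer(y %*% pow) + 1L
      r <- r + 1L
    }
  }
  .br_cache[[key]] <- res
  res
}

#' Canonical form of a truth table under input permutation and negation
#'
#' Returns the representative of the isomorphism orbit: the output vector
#' whose MSB-first serialisation is lexicographically smallest across all
#' k! 2^k input transforms. Two functions are isomorphic iff their canonical
#' forms are equal. Exhaustive, so restricted to k <= 6.
#'
#' @param tt a [truth_table()].
#' @return a [truth_table()] in the same orbit.
#' @export
canonical_form <- function(tt) {
  tt <- as_truth_table(tt)
  if (tt$k > 6L) stop("canonical_form supports k <= 6 (exhaustive transform search)")
  tr <- row_transforms(tt$k)
  cand <- matrix(tt$outputs[tr], nrow = nrow(tr))
  keys <- pack_bits_hex(cand)
  truth_table(cand[order(keys)[1L], ], tt$k)
}

# canonical hex keys for a whole 0/1 matrix of functions (rows = functions,
# cols = cube rows); used by the census and complexity memoization.
canonical_keys_matrix <- function(m, k) {
  tr <- row_transforms(k)
  best <- NULL
  for (r in seq_len(nrow(tr))) {
    keys <- pack_bits_hex(m[, tr[r, ], drop = FALSE])
    best <- if (is.null(best)) keys else pmin(best, keys)
  }
  best
}
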