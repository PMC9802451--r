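#' Average sensitivity and hypercube edge counts
#'
#' The average sensitivity S_f is the mean, over all 2^k input assignments,
#' of the number of Hamming-1 neighbours whose output differs. Geometrically,
#' E01 counts k-cube edges whose endpoints have differing outputs and E11
#' counts edges with both endpoints 1; they satisfy E01 + 2 E11 = k P and
#' S_f = 2 E01 / 2^k, so S_f is reported unnormalised on the scale [0, k]
#' where s ~ 1 marks the critical regime.
#'
#' @param tt a [truth_table()].
#' @return `hypercube_edges()`: named integer vector `c(E01, E11)`;
#'   `average_sensitivity()`: a number in `[0, k]`.
#' @export
hypercube_edges <- function(tt) {
  tt <- as_truth_table(tt)
  e01 <- 0L
  e11 <- 0L
  for (i in seq_len(tt$k)) {
    r0 <- rows_with_bit(tt$k, i, 0L)
    lo <- tt$outputs[r0 + 1L]
    hi <- tt$outputs[r0 + 2^(i - 1L) + 1L]
    e01 <- e01 + sum(lo != hi)
    e11 <- e11 + sum(lo == 1L & hi == 1L)
  }
  c(E01 = e01, E11 = e11)
}

#' @rdname hypercube_edges
#' @export
average_sensitivity <- function(tt) {
  tt <- as_truth_table(tt)
  2 * unname(hypercube_edges(tt)["E01"]) / 2^tt$k
}

# ---- Quine-McCluskey two-level minimization -------------------------------

# prime implicants of the set `ones` (0-based row indices) on k variables;
# an implicant is (v, mask): mask bits are don't-cares, v has 0s there.
qm_prime_implicants <- function(ones, k) {
  cur <- unique(cbind(v = as.integer(ones), mask = 0L))
  primes <- NULL
  while (nrow(cur) > 0L) {
    used <- rep(FALSE, nrow(cur))
    merged <- list()
    for (msk in unique(cur[, 2L])) {
      idx <- which(cur[, 2L] == msk)
      vs <- cur[idx, 1L]
      for (b in 0:(k - 1L)) {
        pb <- bitwShiftL(1L, b)
        if (bitwAnd(msk, pb) != 0L) next
        lo <- vs[bitwAnd(vs, pb) == 0L]
        pair <- lo[(lo + pb) %in% vs]
        if (length(pair)) {
          used[idx[vs %in% c(pair, pair + pb)]] <- TRUE
          merged[[length(merged) + 1L]] <- cbind(v = pair, mask = msk + pb)
        }
      }
    }
    primes <- rbind(primes, cur[!used, , drop = FALSE])
    cur <- if (length(merged)) unique(do.call(rbind, merged)) else
      matrix(integer(), 0L, 2L)
  }
  unique(primes)
}

# exact minimum cover: fewest terms, then fewest literals, then lexicographic
# on the sorted implicant masks (deterministic output).
qm_min_cover <- function(primes, ones, k) {
  full <- 2^k - 1L
  np <- nrow(primes)
  lits <- k - vapply(primes[, 2L], popcount, integer(1))
  covers <- vapply(seq_len(np), function(j) {
    bitwAnd(ones, bitwXor(full, primes[j, 2L])) == primes[j, 1L]
  }, logical(length(ones)))
  covers <- matrix(covers, nrow = length(ones))
  key <- sprintf("%04d%04d", primes[, 2L], primes[, 1L])

  best <- new.env(parent = emptyenv())
  best$terms <- Inf
  best$lits <- Inf
  best$key <- NULL
  best$sel <- NULL

  consider <- function(sel) {
    nt <- length(sel)
    nl <- sum(lits[sel])
    kk <- paste(sort(key[sel]), collapse = "|")
    better <- nt < best$terms ||
      (nt == best$terms && nl < best$lits) ||
      (nt == best$terms && nl == best$lits &&
         (is.null(best$key) || kk < best$key))
    if (better) {
      best$terms <- nt
      best$lits <- nl
      best$key <- kk
      best$sel <- sel
    }
  }

  search <- function(uncovered, sel) {
    if (length(uncovered) == 0L) {
      consider(sel)
      return(invisible(NULL))
    }
    # bound: at least one more term / literal needed
    if (length(sel) + 1L > best$terms) return(invisible(NULL))
    nopts <- rowSums(covers[uncovered, , drop = FALSE])
    row <- uncovered[which.min(nopts)]
    opts <- which(covers[row, ])
    opts <- opts[order(lits[opts], key[opts])]
    for (j in opts) {
      still <- uncovered[!covers[uncovered, j]]
      search(still, c(sel, j))
    }
    invisible(NULL)
  }

  # essential primes first
  sel0 <- integer()
  uncovered <- seq_along(ones)
  repeat {
    cnt <- rowSums(covers[uncovered, , drop = FALSE])
    ess_rows <- uncovered[cnt == 1L]
    if (length(ess_rows) == 0L) break
    ess <- unique(vapply(ess_rows, function(r) which(covers[r, ])[1L],
                         integer(1)))
    sel0 <- c(sel0, ess)
    keep <- !apply(covers[uncovered, ess, drop = FALSE], 1L, any)
    uncovered <- uncovered[keep]
    if (length(uncovered) == 0L) break
  }
  search(uncovered, sel0)
  primes[sort(best$sel), , drop = FALSE]
}

popcount <- function(x) {
  n <- 0L
  while (x > 0L) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

# implicant (v, mask) -> signed literal vector (+i positive, -i negative)
implicant_literals <- function(v, mask, k, negate = FALSE) {
  out <- integer()
  for (b in 0:(k - 1L)) {
    if (bitwAnd(mask, bitwShiftL(1L, b)) != 0L) next
    pos <- bitwAnd(v, bitwShiftL(1L, b)) != 0L
    if (negate) pos <- !pos
    out <- c(out, if (pos) b + 1L else -(b + 1L))
  }
  out
}

terms_to_expr <- function(terms, inner, outer) {
  part <- lapply(terms, function(tm) {
    lits <- lapply(tm, function(l) lit_(abs(l), l < 0L))
    node_(inner, lits)
  })
  node_(outer, part)
}

#' Quine-McCluskey minimization
#'
#' Computes all prime implicants (implicates for CNF) by iterated merging and
#' selects an exact minimum cover via branch-and-bound (fewest terms, then
#' fewest literals, then lexicographic on implicant masks). The CNF route
#' minimizes the complement's DNF and negates through De Morgan.
#'
#' @param tt a non-constant [truth_table()] with k <= 6.
#' @param target `"DNF"` or `"CNF"`.
#' @return a `bool_expr` logically equivalent to `tt`.
#' @export
qm_minimize <- function(tt, target = c("DNF", "CNF")) {
  target <- match.arg(target)
  tt <- as_truth_table(tt)
  if (tt$k > 6L) stop("qm_minimize supports k <= 6")
  if (is_constant_tt(tt)) stop("constant function has no two-level form")
  terms <- qm_terms(tt, target)
  if (target == "DNF") terms_to_expr(terms, "and", "or")
  else terms_to_expr(terms, "or", "and")
}

# minimized term list (signed literal vectors)
qm_terms <- function(tt, target) {
  ones <- if (target == "DNF") which(tt$outputs == 1L) - 1L
          else which(tt$outputs == 0L) - 1L
  primes <- qm_prime_implicants(ones, tt$k)
  sel <- qm_min_cover(primes, ones, tt$k)
  lapply(seq_len(nrow(sel)), function(j) {
    implicant_literals(sel[j, 1L], sel[j, 2L], tt$k, negate = target == "CNF")
  })
}

# ---- algebraic factoring ---------------------------------------------------

# greedy most-frequent-literal division on a term list; `inner` is the
# operator inside a term ("and" for SOP, "or" for POS). Deterministic
# tie-break: lowest variable index, positive before negative.
factor_terms <- function(terms, inner) {
  outer <- if (inner == "and") "or" else "and"
  if (length(terms) == 1L) {
    return(node_(inner, lapply(terms[[1L]], function(l) lit_(abs(l), l < 0L))))
  }
  lits <- unlist(terms)
  tab <- table(lits)
  cnt <- as.integer(tab)
  vals <- as.integer(names(tab))
  mx <- max(cnt)
  if (mx <= 1L) {
    return(terms_to_expr(terms, inner, outer))
  }
  cand <- vals[cnt == mx]
  l <- cand[order(abs(cand), cand < 0L)][1L]
  has <- vapply(terms, function(tm) l %in% tm, logical(1))
  q <- lapply(terms[has], function(tm) tm[tm != l])
  r <- terms[!has]
  if (any(lengths(q) == 0L)) {
    part <- lit_(abs(l), l < 0L)                 # absorption: l (x) (1 ...) = l
  } else {
    part <- node_(inner, list(lit_(abs(l), l < 0L), factor_terms(q, inner)))
  }
  if (length(r) == 0L) part
  else node_(outer, list(part, factor_terms(r, inner)))
}

#' Factor a two-level expression by repeated single-literal division
#'
#' Extracts the most frequent literal as a common divisor, recursively, with
#' a deterministic tie-break (lowest variable index, positive before
#' negative). Works on sum-of-products and product-of-sums forms; for other
#' trees the children are factorized in place. The result is logically
#' equivalent and its literal count never increases.
#'
#' @param e a `bool_expr`.
#' @export
factorize_expr <- function(e) {
  if (e$op == "lit") return(e)
  terms <- two_level_terms(e)
  if (!is.null(terms)) {
    return(factor_terms(terms$terms, terms$inner))
  }
  structure(list(op = e$op, args = lapply(e$args, factorize_expr)),
            class = "bool_expr")
}

# decompose OR-of-ANDs (or AND-of-ORs) of literals into a signed term list
two_level_terms <- function(e) {
  inner <- if (e$op == "or") "and" else "or"
  terms <- vector("list", length(e$args))
  for (j in seq_along(e$args)) {
    a <- e$args[[j]]
    if (a$op == "lit") {
      terms[[j]] <- if (a$neg) -a$var else a$var
    } else if (a$op == inner &&
               all(vapply(a$args, function(x) x$op == "lit", logical(1)))) {
      terms[[j]] <- vapply(a$args, function(x) if (x$neg) -x$var else x$var,
                           integer(1))
    } else {
      return(NULL)
    }
  }
  list(terms = terms, inner = inner)
}

#' Boolean complexity (heuristic upper bound)
#'
#' The Boolean complexity of a function is the literal count of its shortest
#' AND/OR/NOT formula. The estimate takes the best of four factorized seeds:
#' the full DNF, the full CNF, the Quine-McCluskey minimal DNF and the
#' Quine-McCluskey minimal CNF, each passed through [factorize_expr()]. For
#' effective functions the true complexity is at least k, and read-once
#' functions attain exactly k. Use [boolean_complexity_exact()] for a
#' certified value at k <= 4.
#'
#' @param tt a [truth_table()] with k <= 6.
#' @return object of class `complexity_record`: list with
#'   `boolean_complexity`, `source` (winning seed), `exact` (FALSE here),
#'   `expr` (winning factored expression), `average_sensitivity`, `E01`,
#'   `E11`, `k`, `bias`.
#' @export
boolean_complexity <- function(tt) {
  tt <- as_truth_table(tt)
  edges <- hypercube_edges(tt)
  rec <- list(k = tt$k, bias = bias(tt),
              average_sensitivity = 2 * unname(edges["E01"]) / 2^tt$k,
              E01 = unname(edges["E01"]), E11 = unname(edges["E11"]),
              exact = FALSE)
  if (is_constant_tt(tt)) {
    rec$boolean_complexity <- 0L
    rec$source <- "constant"
    rec$expr <- NULL
    return(structure(rec, class = "complexity_record"))
  }
  ones <- which(tt$outputs == 1L) - 1L
  zeros <- which(tt$outputs == 0L) - 1L
  seeds <- list(
    full_dnf = factor_terms(lapply(ones, implicant_literals, mask = 0L,
                                   k = tt$k, negate = FALSE), "and"),
    full_cnf = factor_terms(lapply(zeros, implicant_literals, mask = 0L,
                                   k = tt$k, negate = TRUE), "or"),
    qm_dnf = factor_terms(qm_terms(tt, "DNF"), "and"),
    qm_cnf = factor_terms(qm_terms(tt, "CNF"), "or")
  )
  counts <- vapply(seeds, expr_literal_count, integer(1))
  w <- which.min(counts)
  rec$boolean_complexity <- unname(counts[w])
  rec$source <- names(counts)[w]
  rec$expr <- seeds[[w]]
  structure(rec, class = "complexity_record")
}

#' @export
print.complexity_record <- function(x, ...) {
  cat(sprintf(
    "complexity_record: k=%d P=%d | literals=%d (%s%s) | S=%.4g E01=%d E11=%d\n",
    x$k, x$bias, x$boolean_complexity, x$source,
    if (x$exact) ", exact" else "", x$average_sensitivity, x$E01, x$E11))
  if (!is.null(x$expr)) cat("  expr:", format_expr(x$expr), "\n")
  invisible(x)
}

# ---- exact minimal formula search (small k) --------------------------------

# grow the dynamic program over formula cost for k-input functions: cost-1
# functions are the 2k literals, and every cost-s function is g AND h or
# g OR h with cost(g) + cost(h) = s. Functions are packed integer keys
# (sum of outputs[m] 2^m), valid for k <= 4.
dp_state <- function(k) {
  key <- paste0("dp_", k)
  st <- .br_cache[[key]]
  if (is.null(st)) {
    lits <- vapply(seq_len(k), function(i) {
      v <- bitwAnd(bitwShiftR(0:(2^k - 1), i - 1L), 1L)
      c(sum(v * 2^(0:(2^k - 1))), sum((1L - v) * 2^(0:(2^k - 1))))
    }, numeric(2))
    l1 <- as.integer(lits)
    best <- rep(NA_integer_, 2^(2^k))
    best[l1 + 1L] <- 1L
    st <- list(levels = list(l1), best = best)
    .br_cache[[key]] <- st
  }
  st
}

dp_grow <- function(k, upto, chunk = 2e6) {
  st <- dp_state(k)
  s <- length(st$levels)
  while (s < upto) {
    s <- s + 1L
    new <- integer()
    for (a in 1:(s %/% 2L)) {
      b <- s - a
      la <- st$levels[[a]]
      lb <- st$levels[[b]]
      if (length(la) == 0L || length(lb) == 0L) next
      # stream the la x lb pair block in chunks, marking newly realized
      # functions immediately so later chunks skip them
      step <- max(1L, as.integer(chunk %/% length(lb)))
      for (lo in seq(1L, length(la), by = step)) {
        ga <- la[lo:min(lo + step - 1L, length(la))]
        g <- rep(ga, each = length(lb))
        h <- rep(lb, times = length(ga))
        for (cand in list(bitwAnd(g, h), bitwOr(g, h))) {
          fresh <- unique(cand[is.na(st$best[cand + 1L])])
          if (length(fresh)) {
            st$best[fresh + 1L] <- s
            new <- c(new, fresh)
          }
        }
      }
    }
    st$levels[[s]] <- new
    .br_cache[[paste0("dp_", k)]] <- st
  }
  st
}

#' Exact Boolean complexity by dynamic programming over formula cost
#'
#' Exhaustively realizes every function expressible with s literals, for
#' s = 1, 2, ..., and reports the first cost realizing `tt`. Exact but
#' exponential: restricted to k <= 4 and a literal budget (default 16).
#'
#' @param tt a non-constant [truth_table()] with k <= 4.
#' @param budget maximum formula size to search.
#' @return integer: the minimum literal count.
#' @export
boolean_complexity_exact <- function(tt, budget = 16L) {
  tt <- as_truth_table(tt)
  if (tt$k > 4L) stop("boolean_complexity_exact supports k <= 4")
  if (is_constant_tt(tt)) stop("constant function: no literal formula exists")
  target <- sum(tt$outputs * 2^(0:(2^tt$k - 1)))
  st <- dp_state(tt$k)
  if (!is.na(st$best[target + 1L])) return(st$best[target + 1L])
  s <- length(st$levels)
  while (s < budget) {
    s <- s + 1L
    st <- dp_grow(tt$k, s)
    if (!is.na(st$best[target + 1L])) return(st$best[target + 1L])
  }
  stop("budget of ", budget, " literals exhausted without realizing the function")
}

#' Complexity and sensitivity across the k = 4 function space
#'
#' Computes, for every 4-input function with bias up to `max_bias`, the
#' Boolean-complexity estimate (best of the four factorized seeds, see
#' [boolean_complexity()]) and the average sensitivity. Both quantities are
#' invariant under input isomorphism, so the complexity estimate is computed
#' once per isomorphism class (a few hundred classes instead of tens of
#' thousands of functions) on the class's canonical representative.
#'
#' @param max_bias largest bias retained (default 8; by complementation the
#'   two measures are symmetric about 2^(k-1)).
#' @return data.frame with columns `id`, `bias`, `sensitivity`,
#'   `complexity`; one row per function.
#' @export
complexity_sensitivity_profile <- function(max_bias = 8L) {
  sc <- space_scan(4L)
  keep <- sc$bias <= max_bias
  m <- function_space_bits(4L)
  keys <- canonical_keys_matrix(m[keep, , drop = FALSE], 4L)
  uk <- unique(keys)
  est <- vapply(uk, function(kk) {
    tt <- as_truth_table(kk, k = 4L)
    if (is_constant_tt(tt)) 0L else boolean_complexity(tt)$boolean_complexity
  }, integer(1))
  data.frame(id = sc$id[keep], bias = sc$bias[keep],
             sensitivity = sc$sensitivity[keep],
             complexity = est[match(keys, uk)])
}
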