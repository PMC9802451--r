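# Independent brute-force oracles used to freeze expected values. These are
# deliberately written from the definitions, not via the package internals.

rand_tt <- function(k) {
  truth_table(sample(0:1, 2^k, replace = TRUE), k)
}

# definition-based average sensitivity: loop assignments and single-bit flips
oracle_sensitivity <- function(tt) {
  k <- tt$k
  total <- 0
  for (m in 0:(2^k - 1)) {
    for (i in seq_len(k)) {
      m2 <- bitwXor(m, bitwShiftL(1L, i - 1L))
      total <- total + as.integer(tt$outputs[m + 1L] != tt$outputs[m2 + 1L])
    }
  }
  total / 2^k
}

# definition-based hypercube edge counts
oracle_edges <- function(tt) {
  k <- tt$k
  e01 <- 0L
  e11 <- 0L
  for (m in 0:(2^k - 1)) {
    for (i in seq_len(k)) {
      m2 <- bitwXor(m, bitwShiftL(1L, i - 1L))
      if (m2 > m) {
        a <- tt$outputs[m + 1L]
        b <- tt$outputs[m2 + 1L]
        if (a != b) e01 <- e01 + 1L
        if (a == 1L && b == 1L) e11 <- e11 + 1L
      }
    }
  }
  c(E01 = e01, E11 = e11)
}

# brute-force canonicalization: minimum serialized form over every input
# permutation and negation, built by per-row evaluation
oracle_canonical <- function(tt) {
  k <- tt$k
  perms <- gtools_perms(k)
  best <- NULL
  for (pi in seq_len(nrow(perms))) {
    p <- perms[pi, ]
    for (neg in 0:(2^k - 1)) {
      out <- integer(2^k)
      for (m in 0:(2^k - 1)) {
        x <- bitwAnd(bitwShiftR(m, 0:(k - 1)), 1L)
        y <- integer(k)
        for (i in seq_len(k)) {
          y[i] <- bitwXor(x[p[i]], bitwAnd(bitwShiftR(neg, i - 1L), 1L))
        }
        src <- sum(y * 2^(0:(k - 1)))
        out[m + 1L] <- tt$outputs[src + 1L]
      }
      key <- paste(rev(out), collapse = "")
      if (is.null(best) || key < best$key) best <- list(key = key, out = out)
    }
  }
  truth_table(best$out, k)
}

gtools_perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- gtools_perms(k - 1L)
  out <- NULL
  for (i in seq_len(k)) {
    rest <- seq_len(k)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}

# every bias-P placement of ones on the k-cube (small cases only)
oracle_bias_set_stats <- function(k, P) {
  placements <- utils::combn(2^k, P)
  e11 <- apply(placements, 2L, function(v) {
    out <- integer(2^k)
    out[v] <- 1L
    unname(oracle_edges(truth_table(out, k))["E11"])
  })
  sens <- apply(placements, 2L, function(v) {
    out <- integer(2^k)
    out[v] <- 1L
    oracle_sensitivity(truth_table(out, k))
  })
  list(max_e11 = max(e11), min_sens = min(sens))
}

# direct enumeration of nested chains X1 (x) (X2 (x) (... Xk)) over all
# permutations, signs and operators; independent of the catalog recursion
oracle_ncf_keys <- function(k) {
  perms <- gtools_perms(k)
  keys <- character()
  ops_grid <- as.matrix(expand.grid(rep(list(c("and", "or")), max(k - 1L, 1L))))
  sign_grid <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k)))
  for (pi in seq_len(nrow(perms))) {
    p <- perms[pi, ]
    for (si in seq_len(nrow(sign_grid))) {
      for (oi in seq_len(nrow(ops_grid))) {
        e <- boolrules:::lit_(p[k], sign_grid[si, k])
        if (k > 1L) {
          for (j in (k - 1L):1L) {
            e <- boolrules:::node_(ops_grid[oi, j],
                                   list(boolrules:::lit_(p[j], sign_grid[si, j]), e))
          }
        }
        keys <- c(keys, tt_to_hex(expr_to_tt(e, k)))
      }
    }
  }
  sort(unique(keys))
}

make_tiny_dataset <- function() {
  and2 <- tt_to_string(truth_table(c(0, 0, 0, 1)))
  xor2 <- tt_to_string(truth_table(c(0, 1, 1, 0)))
  reference_dataset(data.frame(
    model_id = rep(c("mA", "mB"), each = 5),
    node_id = paste0("n", 1:10),
    regulators = rep("u,v", 10),
    output_bits = c(rep(and2, 5), rep(xor2, 5))
  ))
}
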