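#' Catalogs of nested canalyzing and read-once functions
#'
#' Generates the complete set of NCF or RoF truth tables on k inputs by
#' recursion over variable subsets with truth-table deduplication at every
#' level: an NCF on a variable set is a signed literal joined by AND/OR to an
#' NCF on the remaining variables; a RoF on a variable set is `g AND h` or
#' `g OR h` for RoFs g, h on a disjoint bipartition (base case: a single
#' signed literal). This produces exactly the sets defined by the nested
#' chain representation and the read-once pairing recursion. Results are
#' memoized per session.
#'
#' Counts for k = 1..6 are 2, 8, 64, 736, 10624, 183920 (NCF) and
#' 2, 8, 64, 832, 15104, 351616 (RoF).
#'
#' @param k number of inputs (1..6 by default bound).
#' @param type `"NCF"`, `"RoF"` or `"nonNCF-RoF"` (set difference).
#' @param kmax configured upper bound on k (cost grows steeply past 6).
#' @return object of class `function_catalog`: list with `k`, `type`,
#'   `count`, and `keys` (hex truth-table serialisations, see [tt_to_hex()]).
#' @export
build_catalog <- function(k, type = c("NCF", "RoF", "nonNCF-RoF"), kmax = 6L) {
  type <- match.arg(type)
  k <- as.integer(k)
  if (k < 1L || k > kmax) stop("catalog supports 1 <= k <= ", kmax)
  key <- paste0("catalog_", type, "_", k)
  if (!is.null(.br_cache[[key]])) return(.br_cache[[key]])
  keys <- switch(type,
    "NCF" = pack_bits_hex(ncf_bits(k)),
    "RoF" = pack_bits_hex(rof_bits(k)),
    "nonNCF-RoF" = setdiff(build_catalog(k, "RoF", kmax)$keys,
                           build_catalog(k, "NCF", kmax)$keys))
  keys <- sort(keys)
  cat_obj <- structure(list(k = k, type = type, count = length(keys),
                            keys = keys),
                       class = "function_catalog")
  .br_cache[[key]] <- cat_obj
  cat_obj
}

#' @export
print.function_catalog <- function(x, ...) {
  cat(sprintf("function_catalog: %s, k = %d, %d truth tables\n",
              x$type, x$k, x$count))
  invisible(x)
}

# 0/1 matrix of the literal x_i (negated or not) over the rows of the k-cube
literal_bits <- function(k, i, neg) {
  v <- bitwAnd(bitwShiftR(0:(2^k - 1), i - 1L), 1L)
  if (neg) 1L - v else v
}

dedup_rows <- function(m) {
  m[!duplicated(pack_bits_hex(m)), , drop = FALSE]
}

# all NCF truth tables over the full k-cube, as a 0/1 matrix (rows = functions)
ncf_bits <- function(k) {
  memo <- new.env(parent = emptyenv())
  rec <- function(vars) {
    id <- paste(vars, collapse = ",")
    if (!is.null(memo[[id]])) return(memo[[id]])
    res <- if (length(vars) == 1L) {
      rbind(literal_bits(k, vars, FALSE), literal_bits(k, vars, TRUE))
    } else {
      parts <- list()
      for (i in vars) {
        sub <- rec(setdiff(vars, i))
        n <- nrow(sub)
        for (neg in c(FALSE, TRUE)) {
          l <- rep(literal_bits(k, i, neg), each = n)
          lm <- matrix(l, nrow = n)
          a <- sub * lm                      # AND
          parts[[length(parts) + 1L]] <- a
          parts[[length(parts) + 1L]] <- sub + lm - a  # OR
        }
      }
      dedup_rows(do.call(rbind, parts))
    }
    memo[[id]] <- res
    res
  }
  rec(seq_len(k))
}

# all RoF truth tables over the full k-cube
rof_bits <- function(k) {
  memo <- new.env(parent = emptyenv())
  rec <- function(vars) {
    id <- paste(vars, collapse = ",")
    if (!is.null(memo[[id]])) return(memo[[id]])
    n <- length(vars)
    res <- if (n == 1L) {
      rbind(literal_bits(k, vars, FALSE), literal_bits(k, vars, TRUE))
    } else {
      rest <- vars[-1L]
      parts <- list()
      for (mask in 0:(2^(n - 1L) - 2L)) {    # S1 contains vars[1]; S2 nonempty
        sel <- bitwAnd(bitwShiftR(mask, 0:(n - 2L)), 1L) == 1L
        s1 <- c(vars[1L], rest[sel])
        s2 <- rest[!sel]
        g <- rec(s1)
        h <- rec(s2)
        ng <- nrow(g)
        nh <- nrow(h)
        gg <- g[rep(seq_len(ng), each = nh), , drop = FALSE]
        hh <- h[rep(seq_len(nh), times = ng), , drop = FALSE]
        a <- gg * hh
        parts[[length(parts) + 1L]] <- a
        parts[[length(parts) + 1L]] <- gg + hh - a
      }
      dedup_rows(do.call(rbind, parts))
    }
    memo[[id]] <- res
    res
  }
  rec(seq_len(k))
}

#' Read-once membership
#'
#' A function is read-once (RoF) when it has an AND/OR/NOT expression in
#' which every variable appears exactly once; RoFs are effective, unate, and
#' have odd bias. Decided by lookup in the complete RoF catalog for k.
#'
#' @param tt a [truth_table()].
#' @param kmax catalog bound (default 6).
#' @export
is_rof <- function(tt, kmax = 6L) {
  tt <- as_truth_table(tt)
  if (tt$k > kmax) stop("is_rof: k exceeds the catalog bound (", kmax, ")")
  tt_to_hex(tt) %in% build_catalog(tt$k, "RoF", kmax)$keys
}

#' Write / read a catalog cache file
#'
#' Plain-text format: first line a JSON header
#' (`k`, `type`, `count`, `bit_order` = "msb"), then one hex truth table per
#' line.
#' @param catalog a `function_catalog`.
#' @param path file path.
#' @export
write_catalog <- function(catalog, path) {
  header <- jsonlite::toJSON(list(k = catalog$k, type = catalog$type,
                                  count = catalog$count, bit_order = "msb"),
                             auto_unbox = TRUE)
  writeLines(c(as.character(header), catalog$keys), path)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1L])
  keys <- lines[-1L]
  if (length(keys) != header$count) stop("catalog file corrupt: count mismatch")
  structure(list(k = header$k, type = header$type, count = header$count,
                 keys = keys),
            class = "function_catalog")
}

#' Truth tables of a catalog
#' @param catalog a `function_catalog`.
#' @return list of [truth_table()] objects.
#' @export
catalog_tts <- function(catalog) {
  lapply(catalog$keys, hex_to_tt, k = catalog$k)
}
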