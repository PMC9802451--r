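#' Effective inputs of a Boolean function
#'
#' Input i is effective iff flipping x_i changes the output for at least one
#' assignment of the other inputs. A function is effective (EF) when all its
#' declared inputs are effective; biologically, an ineffective input should
#' not be counted as a regulator at all.
#'
#' @param tt a [truth_table()].
#' @return integer vector of effective input indices.
#' @export
effective_inputs <- function(tt) {
  tt <- as_truth_table(tt)
  which(vapply(seq_len(tt$k), function(i) input_matters(tt, i), logical(1)))
}

input_matters <- function(tt, i) {
  r0 <- rows_with_bit(tt$k, i, 0L)
  any(tt$outputs[r0 + 1L] != tt$outputs[r0 + 2^(i - 1L) + 1L])
}

#' @rdname effective_inputs
#' @export
is_effective <- function(tt) {
  tt <- as_truth_table(tt)
  length(effective_inputs(tt)) == tt$k
}

#' Drop ineffective inputs
#'
#' Restricts a function to its effective inputs (renumbered 1..k' in
#' ascending original order). Fixing the ineffective inputs to any values
#' yields the same reduced function; constants cannot be truncated.
#'
#' @param tt a [truth_table()].
#' @return a list with `tt` (the reduced [truth_table()]) and
#'   `kept` (original indices of the effective inputs).
#' @export
truncate_ineffective <- function(tt) {
  tt <- as_truth_table(tt)
  eff <- effective_inputs(tt)
  if (length(eff) == 0L) stop("constant function: no effective inputs to keep")
  if (length(eff) == tt$k) return(list(tt = tt, kept = eff))
  kp <- length(eff)
  m <- 0:(2^kp - 1)
  src <- integer(2^kp)
  for (j in seq_along(eff)) {
    src <- src + bitwAnd(bitwShiftR(m, j - 1L), 1L) * 2^(eff[j] - 1L)
  }
  list(tt = truth_table(tt$outputs[src + 1L], kp), kept = eff)
}

#' Regulatory sign of each input
#'
#' An input is `activating` when the output is monotone non-decreasing in it,
#' `inhibiting` when non-increasing, `both` when both hold (which forces the
#' input to be ineffective), and `mixed` otherwise. A function is unate (UF)
#' iff no input is `mixed`.
#'
#' @param tt a [truth_table()].
#' @param i input index.
#' @return `input_sign()`: one of `"activating"`, `"inhibiting"`, `"both"`,
#'   `"mixed"`. `input_signs()`: character vector over all inputs.
#' @export
input_sign <- function(tt, i) {
  tt <- as_truth_table(tt)
  r0 <- rows_with_bit(tt$k, i, 0L)
  lo <- tt$outputs[r0 + 1L]
  hi <- tt$outputs[r0 + 2^(i - 1L) + 1L]
  act <- all(lo <= hi)
  inh <- all(lo >= hi)
  if (act && inh) "both" else if (act) "activating" else if (inh) "inhibiting" else "mixed"
}

#' @rdname input_sign
#' @export
input_signs <- function(tt) {
  tt <- as_truth_table(tt)
  vapply(seq_len(tt$k), function(i) input_sign(tt, i), character(1))
}

#' @rdname input_sign
#' @export
is_unate <- function(tt) {
  !any(input_signs(tt) == "mixed")
}

#' Canalyzing inputs of a Boolean function
#'
#' Input i is canalyzing with canalyzing value a and canalyzed value b when
#' fixing x_i = a forces the output to b regardless of all other inputs. A
#' function is canalyzing (CF) when at least one (i, a, b) triple exists;
#' constants satisfy this for every input and value.
#'
#' @param tt a [truth_table()].
#' @return `canalyzing_inputs()`: data.frame with columns `input`, `value`
#'   (a), `output` (b); zero rows when the function is not canalyzing.
#' @export
canalyzing_inputs <- function(tt) {
  tt <- as_truth_table(tt)
  res <- list()
  for (i in seq_len(tt$k)) {
    for (a in 0:1) {
      out <- tt$outputs[rows_with_bit(tt$k, i, a) + 1L]
      if (all(out == out[1L])) {
        res[[length(res) + 1L]] <- c(i, a, out[1L])
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(input = integer(), value = integer(), output = integer()))
  }
  m <- do.call(rbind, res)
  data.frame(input = m[, 1L], value = m[, 2L], output = m[, 3L])
}

#' @rdname canalyzing_inputs
#' @export
is_canalyzing <- function(tt) {
  nrow(canalyzing_inputs(tt)) > 0L
}

#' Nested canalyzing test
#'
#' A function is nested canalyzing (NCF) when it has a canalyzing input whose
#' restriction to the non-canalyzing value is recursively nested canalyzing,
#' bottoming out at a single literal. Equivalently the function can be written
#' as a right-nested chain of signed literals joined by AND/OR with exactly k
#' literals. Returns the first witness chain under ascending input index and
#' canalyzing value 0 before 1.
#'
#' @param tt a [truth_table()].
#' @param witness if `TRUE`, return the chain as a data.frame
#'   (`input`, `value`, `output` per nesting level, original input indices)
#'   in an attribute `chain` of the result.
#' @return logical flag.
#' @export
is_ncf <- function(tt, witness = FALSE) {
  tt <- as_truth_table(tt)
  chain <- ncf_chain(tt$outputs, tt$k, seq_len(tt$k))
  ok <- !is.null(chain)
  if (witness && ok) attr(ok, "chain") <- do.call(rbind, chain)
  ok
}

# recursive witness search; vars maps current positions to original indices
ncf_chain <- function(out, k, vars) {
  if (k == 1L) {
    if (out[1L] == out[2L]) return(NULL)  # constant, not a literal
    return(list(data.frame(input = vars[1L], value = NA_integer_,
                           output = NA_integer_)))
  }
  for (i in seq_len(k)) {
    for (a in 0:1) {
      ra <- rows_with_bit(k, i, a) + 1L
      fixed <- out[ra]
      if (all(fixed == fixed[1L])) {
        rest <- out[rows_with_bit(k, i, 1L - a) + 1L]
        sub <- ncf_chain(rest, k - 1L, vars[-i])
        if (!is.null(sub)) {
          return(c(list(data.frame(input = vars[i], value = a,
                                   output = fixed[1L])), sub))
        }
      }
    }
  }
  NULL
}

#' Full type profile of a Boolean function
#'
#' Runs every classifier and returns a `type_profile` record: bias and its
#' parity, effectiveness, per-input signs, unateness, canalyzing triples, and
#' NCF / read-once membership. Read-once status needs the catalog and is `NA`
#' when k exceeds the catalog bound.
#'
#' @param tt a [truth_table()].
#' @param rof_kmax largest k for which read-once membership is resolved via
#'   the catalog (default 6).
#' @return object of class `type_profile`.
#' @export
classify_bf <- function(tt, rof_kmax = 6L) {
  tt <- as_truth_table(tt)
  p <- bias(tt)
  signs <- input_signs(tt)
  can <- canalyzing_inputs(tt)
  eff <- effective_inputs(tt)
  ncf <- is_ncf(tt)
  rof <- if (tt$k <= rof_kmax) is_rof(tt) else NA
  structure(list(
    k = tt$k,
    bias = p,
    parity = if (p %% 2L == 1L) "odd" else "even",
    is_effective = length(eff) == tt$k,
    ineffective_inputs = setdiff(seq_len(tt$k), eff),
    input_signs = signs,
    is_unate = !any(signs == "mixed"),
    is_canalyzing = nrow(can) > 0L,
    canalyzing_inputs = can,
    is_ncf = ncf,
    is_rof = rof
  ), class = "type_profile")
}

#' @export
print.type_profile <- function(x, ...) {
  flags <- c(EF = x$is_effective, UF = x$is_unate, CF = x$is_canalyzing,
             NCF = x$is_ncf, RoF = x$is_rof)
  lab <- vapply(names(flags), function(nm) {
    v <- flags[[nm]]
    paste0(nm, "=", if (is.na(v)) "NA" else if (v) "yes" else "no")
  }, character(1))
  cat(sprintf("type_profile: k=%d P=%d (%s) | %s\n", x$k, x$bias, x$parity,
              paste(lab, collapse = " ")))
  cat("  input signs:", paste(x$input_signs, collapse = ", "), "\n")
  invisible(x)
}
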