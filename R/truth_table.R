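#' Truth table of a Boolean function
#'
#' A `truth_table` stores a k-input Boolean function as its output column: an
#' integer vector of 2^k zeros and ones. The output for the input assignment
#' (x_1, ..., x_k) sits at row index m = sum_i x_i 2^(i-1), i.e. x_1 is the
#' least-significant bit of the row index. Text serialisations print the rows
#' most-significant-first, so the printed string reads from the all-ones
#' assignment down to the all-zeros assignment (use `bit_order = "lsb"` for
#' the opposite dialect).
#'
#' @param outputs vector of 2^k values coercible to 0/1.
#' @param k number of inputs; inferred from `length(outputs)` when missing.
#' @return an object of class `truth_table`.
#' @examples
#' and2 <- truth_table(c(0, 0, 0, 1))   # rows 00, 01, 10, 11
#' bias(and2)
#' @export
truth_table <- function(outputs, k = NULL) {
  outputs <- as.integer(outputs)
  if (is.null(k)) {
    k <- as.integer(round(log2(length(outputs))))
  }
  if (k < 1L || k > 10L) {
    stop("k must be between 1 and 10")
  }
  if (length(outputs) != 2^k) {
    stop("length(outputs) must equal 2^k")
  }
  if (anyNA(outputs) || !all(outputs %in% c(0L, 1L))) {
    stop("outputs must all be 0 or 1")
  }
  structure(list(k = k, outputs = outputs), class = "truth_table")
}

#' Coerce bit strings, hex strings or vectors to a truth table
#'
#' Accepts a `truth_table`, a 0/1 vector, a bit string such as `"0001"`
#' (MSB-first row order by default), or a hex string such as `"0x8"` /
#' `"8e41"` (each hex digit covers 4 rows, MSB-first).
#'
#' @param x object to coerce.
#' @param k number of inputs; required for hex strings whose width is
#'   ambiguous, otherwise inferred.
#' @param bit_order `"msb"` (default) or `"lsb"`: whether the first character
#'   of a bit string is the all-ones row or the all-zeros row.
#' @export
as_truth_table <- function(x, k = NULL, bit_order = c("msb", "lsb")) {
  bit_order <- match.arg(bit_order)
  if (inherits(x, "truth_table")) {
    return(x)
  }
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    s <- sub("^0[xX]", "", x)
    if (grepl("^[01]+$", s) && (is.null(k) || nchar(s) == 2^k)) {
      bits <- as.integer(strsplit(s, "")[[1]])
    } else if (grepl("^[0-9a-fA-F]+$", s)) {
      digs <- strtoi(strsplit(tolower(s), "")[[1]], base = 16L)
      bits <- as.vector(vapply(digs, function(d) {
        as.integer(bitwAnd(bitwShiftR(d, 3:0), 1L))
      }, integer(4)))
      if (!is.null(k)) {
        bits <- bits[(length(bits) - 2^k + 1):length(bits)]
      }
    } else {
      stop("cannot parse '", x, "' as a truth table")
    }
    if (bit_order == "msb") {
      bits <- rev(bits)
    }
    return(truth_table(bits, k))
  }
  truth_table(x, k)
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("truth_table: k = %d, bias = %d, bits (x_%d..x_1) = %s\n",
              x$k, bias(x), x$k, tt_to_string(x)))
  invisible(x)
}

#' @export
format.truth_table <- function(x, ...) tt_to_string(x)

#' Serialise a truth table as a bit string
#'
#' @param tt a [truth_table()].
#' @param bit_order `"msb"` (default, row 2^k - 1 first) or `"lsb"`.
#' @export
tt_to_string <- function(tt, bit_order = c("msb", "lsb")) {
  bit_order <- match.arg(bit_order)
  bits <- tt$outputs
  if (bit_order == "msb") bits <- rev(bits)
  paste(bits, collapse = "")
}

#' Serialise a truth table as a hex string (MSB-first rows)
#'
#' The key used by the function catalogs: 2^k bits, most-significant row
#' first, packed into ceiling(2^k / 4) hex digits.
#' @param tt a [truth_table()].
#' @export
tt_to_hex <- function(tt) {
  pack_bits_hex(matrix(tt$outputs, nrow = 1L))
}

#' Decode a catalog hex key back into a truth table
#' @param hex hex string as produced by [tt_to_hex()].
#' @param k number of inputs.
#' @export
hex_to_tt <- function(hex, k) {
  as_truth_table(hex, k = k)
}

# Pack rows of a 0/1 matrix (columns = cube rows 0..2^k-1) into hex keys,
# MSB-first. Vectorised over matrix rows.
pack_bits_hex <- function(m) {
  nb <- ncol(m)
  if (nb < 4L) {                      # k = 1: one hex digit from 2 bits
    digit <- m[, 2L] * 2L + m[, 1L]
    return(c("0", "1", "2", "3")[digit + 1L])
  }
  hexdig <- c(0:9, letters[1:6])
  pieces <- vector("list", nb %/% 4L)
  for (j in seq_along(pieces)) {
    hi <- nb - 4L * (j - 1L)          # descending row indices (1-based cols)
    digit <- m[, hi] * 8L + m[, hi - 1L] * 4L + m[, hi - 2L] * 2L + m[, hi - 3L]
    pieces[[j]] <- hexdig[digit + 1L]
  }
  do.call(paste0, pieces)
}

#' Bias of a Boolean function
#'
#' The number of input assignments for which the function outputs 1; the
#' functions with given k and bias P form the k[P] set.
#' @param tt a [truth_table()] (or anything [as_truth_table()] accepts).
#' @return integer in `[0, 2^k]`.
#' @export
bias <- function(tt) {
  tt <- as_truth_table(tt)
  sum(tt$outputs)
}

#' Complement of a Boolean function
#'
#' Flips every output bit; the result lies in the k[2^k - P] set and has the
#' same average sensitivity as the input.
#' @param tt a [truth_table()].
#' @export
tt_complement <- function(tt) {
  tt <- as_truth_table(tt)
  truth_table(1L - tt$outputs, tt$k)
}

#' @export
`==.truth_table` <- function(e1, e2) {
  e1$k == e2$k && all(e1$outputs == e2$outputs)
}

is_constant_tt <- function(tt) {
  p <- sum(tt$outputs)
  p == 0L || p == length(tt$outputs)
}

# row indices (0-based) of assignments with x_i = v, for a k-cube
rows_with_bit <- function(k, i, v) {
  m <- 0:(2^k - 1)
  m[bitwAnd(bitwShiftR(m, i - 1L), 1L) == v]
}
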