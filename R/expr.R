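#' Boolean expression trees
#'
#' Expressions are stored in negation normal form (NNF): negations only on
#' literals, internal nodes are n-ary AND / OR. Node structure:
#' `list(op = "lit", var = i, neg = TRUE/FALSE)` or
#' `list(op = "and"/"or", args = list(...))`. The number of literal leaves is
#' the quantity Boolean complexity counts.
#'
#' @name bool_expr
NULL

lit_ <- function(var, neg = FALSE) {
  structure(list(op = "lit", var = as.integer(var), neg = isTRUE(neg)),
            class = "bool_expr")
}

node_ <- function(op, args) {
  stopifnot(op %in% c("and", "or"), length(args) >= 1L)
  if (length(args) == 1L) return(args[[1L]])
  # flatten nested nodes of the same operator
  flat <- list()
  for (a in args) {
    if (!inherits(a, "bool_expr")) stop("non-expression child")
    if (a$op == op) flat <- c(flat, a$args) else flat <- c(flat, list(a))
  }
  structure(list(op = op, args = flat), class = "bool_expr")
}

#' Number of literal leaves in an expression
#' @param e a `bool_expr`.
#' @export
expr_literal_count <- function(e) {
  if (e$op == "lit") return(1L)
  sum(vapply(e$args, expr_literal_count, integer(1)))
}

#' Parse a Boolean expression string
#'
#' Grammar: variables `x1..xk`; negation prefix `~` or `!`; AND by `&` or
#' juxtaposition; OR by `+` or `|`; parentheses. Negations (including negated
#' parentheses) are pushed onto literals at parse time, so the result is in
#' NNF and literal counting is well defined.
#'
#' @param text expression string, e.g. `"~x1 & (~x2 | ~x3)"` or `"x1x2(x3+x4)"`.
#' @return a `bool_expr`.
#' @export
parse_expr <- function(text) {
  toks <- tokenize_expr(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  e <- parse_or(st)
  if (st$pos <= length(st$toks)) {
    t <- st$toks[[st$pos]]
    stop(sprintf("syntax error at position %d: unexpected '%s'", t$at, t$text))
  }
  e
}

tokenize_expr <- function(text) {
  chars <- strsplit(text, "")[[1]]
  toks <- list()
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) {
      i <- i + 1L
    } else if (ch %in% c("~", "!", "&", "+", "|", "(", ")")) {
      type <- switch(ch, "~" = "not", "!" = "not", "&" = "and",
                     "+" = "or", "|" = "or", "(" = "lpar", ")" = "rpar")
      toks[[length(toks) + 1L]] <- list(type = type, text = ch, at = i)
      i <- i + 1L
    } else if (ch == "x") {
      j <- i + 1L
      while (j <= n && grepl("^[0-9]$", chars[j])) j <- j + 1L
      if (j == i + 1L) stop(sprintf("syntax error at position %d: 'x' needs an index", i))
      idx <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      toks[[length(toks) + 1L]] <- list(type = "var", text = paste0("x", idx),
                                        at = i, var = idx)
      i <- j
    } else {
      stop(sprintf("syntax error at position %d: unexpected '%s'", i, ch))
    }
  }
  if (length(toks) == 0L) stop("syntax error: empty expression")
  toks
}

peek_tok <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL

parse_or <- function(st) {
  args <- list(parse_and(st))
  repeat {
    t <- peek_tok(st)
    if (is.null(t) || t$type != "or") break
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- parse_and(st)
  }
  node_("or", args)
}

parse_and <- function(st) {
  args <- list(parse_unary(st))
  repeat {
    t <- peek_tok(st)
    if (is.null(t)) break
    if (t$type == "and") {
      st$pos <- st$pos + 1L
      args[[length(args) + 1L]] <- parse_unary(st)
    } else if (t$type %in% c("var", "not", "lpar")) {
      args[[length(args) + 1L]] <- parse_unary(st)  # juxtaposition
    } else break
  }
  node_("and", args)
}

parse_unary <- function(st) {
  t <- peek_tok(st)
  if (is.null(t)) stop("syntax error: unexpected end of expression")
  if (t$type == "not") {
    st$pos <- st$pos + 1L
    negate_expr(parse_unary(st))
  } else if (t$type == "var") {
    st$pos <- st$pos + 1L
    if (t$var < 1L) stop(sprintf("syntax error at position %d: bad index", t$at))
    lit_(t$var)
  } else if (t$type == "lpar") {
    st$pos <- st$pos + 1L
    e <- parse_or(st)
    t2 <- peek_tok(st)
    if (is.null(t2) || t2$type != "rpar") {
      stop(sprintf("syntax error at position %d: expected ')'", t$at))
    }
    st$pos <- st$pos + 1L
    e
  } else {
    stop(sprintf("syntax error at position %d: unexpected '%s'", t$at, t$text))
  }
}

# De Morgan push-down: keeps the tree in NNF
negate_expr <- function(e) {
  if (e$op == "lit") return(lit_(e$var, !e$neg))
  op <- if (e$op == "and") "or" else "and"
  node_(op, lapply(e$args, negate_expr))
}

#' Format a Boolean expression as a string
#'
#' Prints with explicit `&` and `|`; output re-parses to an equivalent
#' function: `expr_to_tt(parse_expr(format_expr(e)), k)` equals
#' `expr_to_tt(e, k)`.
#' @param e a `bool_expr`.
#' @export
format_expr <- function(e) {
  if (e$op == "lit") return(paste0(if (e$neg) "~" else "", "x", e$var))
  if (e$op == "and") {
    parts <- vapply(e$args, function(a) {
      s <- format_expr(a)
      if (a$op == "or") paste0("(", s, ")") else s
    }, character(1))
    return(paste(parts, collapse = " & "))
  }
  paste(vapply(e$args, format_expr, character(1)), collapse = " | ")
}

#' @export
print.bool_expr <- function(x, ...) {
  cat(format_expr(x), "\n")
  invisible(x)
}

#' Highest variable index occurring in an expression
#' @param e a `bool_expr`.
#' @export
expr_max_var <- function(e) {
  if (e$op == "lit") return(e$var)
  max(vapply(e$args, expr_max_var, integer(1)))
}

#' Evaluate an expression into a truth table
#'
#' @param e a `bool_expr`.
#' @param k number of inputs (must cover every variable index in `e`).
#' @return a [truth_table()].
#' @export
expr_to_tt <- function(e, k) {
  k <- as.integer(k)
  if (expr_max_var(e) > k) stop("variable index exceeds k")
  m <- 0:(2^k - 1)
  truth_table(as.integer(eval_expr_rows(e, m)), k)
}

eval_expr_rows <- function(e, m) {
  if (e$op == "lit") {
    v <- bitwAnd(bitwShiftR(m, e$var - 1L), 1L) == 1L
    return(if (e$neg) !v else v)
  }
  vals <- lapply(e$args, eval_expr_rows, m = m)
  if (e$op == "and") Reduce(`&`, vals) else Reduce(`|`, vals)
}
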