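#' Reference datasets of regulatory rules
#'
#' A reference dataset is a collection of (model, node, rule) records, one
#' Boolean update rule per node of each network model. Stored as a
#' data.frame with columns `model_id`, `node_id`, `regulators`
#' (comma-separated input names, in x_1..x_k order), `k`, and `output_bits`
#' (MSB-first bit string of the rule's truth table, see [tt_to_string()]).
#'
#' @param records data.frame with the columns above (`k` is recomputed from
#'   `output_bits` when absent).
#' @return object of class `reference_dataset` (a data.frame).
#' @export
reference_dataset <- function(records) {
  need <- c("model_id", "node_id", "regulators", "output_bits")
  if (!all(need %in% names(records))) {
    stop("records must have columns ", paste(need, collapse = ", "))
  }
  records$k <- as.integer(round(log2(nchar(records$output_bits))))
  if (any(2^records$k != nchar(records$output_bits))) {
    stop("output_bits lengths must be powers of two")
  }
  bad <- grepl("[^01]", records$output_bits)
  if (any(bad)) stop("output_bits must be 0/1 strings")
  class(records) <- c("reference_dataset", "data.frame")
  records
}

#' @export
print.reference_dataset <- function(x, ...) {
  cat(sprintf("reference_dataset: %d rules, %d models, in-degrees %s\n",
              nrow(x), length(unique(x$model_id)),
              paste(sort(unique(x$k)), collapse = ",")))
  print(utils::head(as.data.frame(x)), row.names = FALSE)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' Read / write a rules TSV file
#'
#' Tab-separated with header `model_id node_id regulators output_bits`;
#' `regulators` is a comma list and `output_bits` an MSB-first bit string.
#' @param path file path.
#' @export
read_rules_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, colClasses = "character")
  reference_dataset(df)
}

#' @rdname read_rules_tsv
#' @param ds a [reference_dataset()].
#' @export
write_rules_tsv <- function(ds, path) {
  utils::write.table(ds[, c("model_id", "node_id", "regulators", "output_bits")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BoolNet-style expression file
#'
#' Expects a `targets, factors` header followed by `node, expression` lines,
#' with `&`, `|`, `!` and parentheses in the expressions. Each rule's
#' regulators are the node names in order of first occurrence in its
#' expression, and the expression is compiled to a truth table over them.
#'
#' @param path file path.
#' @param model_id model identifier for the resulting records.
#' @export
read_boolnet <- function(path, model_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (!grepl("^targets\\s*,\\s*factors", lines[1L], ignore.case = TRUE)) {
    stop("not a BoolNet file: expected 'targets, factors' header")
  }
  recs <- lapply(lines[-1L], function(ln) {
    parts <- strsplit(ln, ",")[[1L]]
    if (length(parts) < 2L) stop("malformed BoolNet line: ", ln)
    target <- trimws(parts[1L])
    rhs <- trimws(paste(parts[-1L], collapse = ","))
    vars <- unique(regmatches(rhs, gregexpr("[A-Za-z_][A-Za-z0-9_]*", rhs))[[1L]])
    expr_txt <- rhs
    for (j in seq_along(vars)) {
      expr_txt <- gsub(paste0("\\b", vars[j], "\\b"), paste0("@", j), expr_txt)
    }
    expr_txt <- gsub("@", "x", expr_txt, fixed = TRUE)
    tt <- expr_to_tt(parse_expr(expr_txt), length(vars))
    data.frame(model_id = model_id, node_id = target,
               regulators = paste(vars, collapse = ","),
               output_bits = tt_to_string(tt))
  })
  reference_dataset(do.call(rbind, recs))
}

# truth tables of the records (list), computed on demand
dataset_tts <- function(ds) {
  lapply(seq_len(nrow(ds)), function(r) {
    as_truth_table(ds$output_bits[r], k = ds$k[r])
  })
}

# does tt belong to the labelled type? NA when RoF status is undecidable
type_flag <- function(tt, type, rof_kmax = 6L) {
  switch(type,
    EF = is_effective(tt),
    UF = is_unate(tt),
    CF = is_canalyzing(tt),
    ECF = is_effective(tt) && is_canalyzing(tt),
    EUF = is_effective(tt) && is_unate(tt),
    NCF = is_ncf(tt),
    RoF = if (tt$k <= rof_kmax) is_rof(tt) else NA,
    `nonNCF-RoF` = if (tt$k <= rof_kmax) is_rof(tt) && !is_ncf(tt) else NA,
    odd = bias(tt) %% 2L == 1L,
    even = bias(tt) %% 2L == 0L,
    stop("unknown type '", type, "'"))
}

#' Relative abundance of a function type in a reference dataset
#'
#' Fraction of the k-input rules that belong to the type. Rules whose
#' read-once status cannot be resolved (k above the catalog bound) are
#' reported via a message and count as non-members.
#'
#' @param ds a [reference_dataset()].
#' @param type type label (`"EF"`, `"UF"`, `"CF"`, `"ECF"`, `"EUF"`,
#'   `"NCF"`, `"RoF"`, `"nonNCF-RoF"`, `"odd"`, `"even"`).
#' @param k in-degree to restrict to.
#' @export
relative_abundance <- function(ds, type, k) {
  sub <- ds[ds$k == k, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rules with k = ", k, " in the dataset")
  flags <- vapply(dataset_tts(sub), type_flag, logical(1), type = type)
  if (anyNA(flags)) {
    message(sum(is.na(flags)), " rule(s) with unresolved ", type,
            " status (k beyond catalog bound) counted as non-members")
    flags[is.na(flags)] <- FALSE
  }
  mean(flags)
}

#' Enrichment of a type against the random-function ensemble
#'
#' Compares the abundance f1 of a type among the k-input reference rules to
#' its abundance f0 in the space of all k-input functions. The enrichment
#' ratio is E = f1/f0 and the significance is the exact one-sided binomial
#' tail P(X >= count | n_k, f0) under the null that reference rules are
#' drawn uniformly from all functions.
#'
#' @inheritParams relative_abundance
#' @param f0 the full-space fraction of the type; computed from the census
#'   or catalogs when omitted (possible for odd/even at any k, RoF-family
#'   types at k <= 6, and everything at k <= 4).
#' @return an `enrichment_result`: one-row data.frame with `k`, `type`,
#'   `n`, `count`, `f0`, `f1`, `E`, `p_value`.
#' @export
enrichment_test <- function(ds, type, k, f0 = NULL) {
  if (is.null(f0)) f0 <- full_space_fraction(type, k)
  if (!is.numeric(f0) || f0 <= 0 || f0 >= 1) {
    stop("f0 must lie strictly between 0 and 1")
  }
  sub <- ds[ds$k == k, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rules with k = ", k, " in the dataset")
  n <- nrow(sub)
  cnt <- round(relative_abundance(ds, type, k) * n)
  res <- data.frame(k = k, type = type, n = n, count = cnt, f0 = f0,
                    f1 = cnt / n, E = (cnt / n) / f0,
                    p_value = stats::pbinom(cnt - 1L, n, f0, lower.tail = FALSE))
  class(res) <- c("enrichment_result", "data.frame")
  res
}

full_space_fraction <- function(type, k) {
  if (type %in% c("odd", "even")) return(0.5)
  if (type %in% c("NCF", "RoF", "nonNCF-RoF") && k <= 6L) {
    return(build_catalog(k, type)$count / 2^(2^k))
  }
  if (k > 4L) stop("f0 for type ", type, " at k = ", k,
                   " must be supplied explicitly")
  sc <- space_scan(k)
  num <- switch(type,
                EF = sc$effective, UF = sc$unate, CF = sc$canalyzing,
                ECF = sc$effective & sc$canalyzing,
                EUF = sc$effective & sc$unate,
                stop("unknown type '", type, "'"))
  sum(num) / nrow(sc)
}

#' Relative enrichment of a subtype within an englobing type
#'
#' Tests whether a subtype's enrichment merely reflects the enrichment of a
#' type containing it: under the null, the reference rules of the englobing
#' type draw their subtype membership with the full-space conditional
#' probability f_s0/f0. Reports
#' E_R = (f_s1/f1) / (f_s0/f0) and the exact one-sided binomial tail with
#' n = reference count of the englobing type.
#'
#' @inheritParams relative_abundance
#' @param subtype,within type labels; the subtype must be contained in
#'   `within` for the ratio to be meaningful (e.g. NCF within CF or RoF).
#' @export
relative_enrichment_test <- function(ds, subtype, within, k) {
  sub <- ds[ds$k == k, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rules with k = ", k, " in the dataset")
  tts <- dataset_tts(sub)
  in_type <- vapply(tts, type_flag, logical(1), type = within)
  in_sub <- vapply(tts, type_flag, logical(1), type = subtype)
  in_type[is.na(in_type)] <- FALSE
  in_sub[is.na(in_sub)] <- FALSE
  n <- sum(in_type)
  if (n == 0L) stop("no ", within, " rules with k = ", k, " in the dataset")
  x <- sum(in_sub & in_type)
  p0 <- subtype_fraction(k, subtype, within)
  res <- data.frame(k = k, subtype = subtype, within = within, n = n,
                    count = x, fs0_over_f0 = p0, fs1_over_f1 = x / n,
                    E_R = (x / n) / p0,
                    p_value = stats::pbinom(x - 1L, n, p0, lower.tail = FALSE))
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Replace ineffective rules by their truncated effective versions
#'
#' Every rule with ineffective inputs is re-keyed to its effective inputs
#' only (see [truncate_ineffective()]); constant rules cannot be truncated
#' and are dropped with a warning.
#'
#' @param ds a [reference_dataset()].
#' @export
truncated_view <- function(ds) {
  keep <- rep(TRUE, nrow(ds))
  for (r in seq_len(nrow(ds))) {
    tt <- as_truth_table(ds$output_bits[r], k = ds$k[r])
    eff <- effective_inputs(tt)
    if (length(eff) == 0L) {
      keep[r] <- FALSE
      next
    }
    if (length(eff) < tt$k) {
      tr <- truncate_ineffective(tt)
      regs <- strsplit(ds$regulators[r], ",")[[1L]]
      ds$regulators[r] <- paste(regs[tr$kept], collapse = ",")
      ds$output_bits[r] <- tt_to_string(tr$tt)
      ds$k[r] <- tr$tt$k
    }
  }
  if (any(!keep)) {
    warning(sum(!keep), " constant rule(s) dropped in truncated view")
  }
  reference_dataset(as.data.frame(ds[keep, , drop = FALSE]))
}
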