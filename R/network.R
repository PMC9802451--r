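#' Boolean network models
#'
#' A model is a set of named nodes, each with an ordered regulator list and
#' an update rule (a [truth_table()] whose k equals the in-degree; the i-th
#' regulator is input x_i). Self-loops and external inputs count as ordinary
#' regulators.
#'
#' @param nodes character vector of node names.
#' @param regulators list of character vectors, one per node.
#' @param rules list of [truth_table()] objects, one per node.
#' @param id optional model identifier.
#' @return object of class `boolean_network`.
#' @export
boolean_network <- function(nodes, regulators, rules, id = "model") {
  stopifnot(length(nodes) == length(regulators),
            length(nodes) == length(rules))
  rules <- lapply(rules, as_truth_table)
  for (i in seq_along(nodes)) {
    if (rules[[i]]$k != length(regulators[[i]])) {
      stop("node ", nodes[i], ": rule has k = ", rules[[i]]$k,
           " but ", length(regulators[[i]]), " regulators")
    }
  }
  structure(list(id = id, nodes = nodes, regulators = regulators,
                 rules = rules),
            class = "boolean_network")
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("boolean_network '%s': %d nodes, in-degrees %s\n", x$id,
              length(x$nodes),
              paste(range(vapply(x$rules, function(r) r$k, integer(1))),
                    collapse = "-")))
  invisible(x)
}

#' Split a reference dataset into its network models
#' @param ds a [reference_dataset()].
#' @return list of [boolean_network()] objects.
#' @export
models_from_dataset <- function(ds) {
  lapply(split(seq_len(nrow(ds)), ds$model_id), function(rows) {
    sub <- ds[rows, , drop = FALSE]
    boolean_network(sub$node_id,
                    strsplit(sub$regulators, ","),
                    lapply(seq_len(nrow(sub)), function(r) {
                      as_truth_table(sub$output_bits[r], k = sub$k[r])
                    }),
                    id = sub$model_id[1L])
  })
}

#' Network average sensitivity
#'
#' The mean over all nodes of each node rule's average sensitivity; s ~ 1 is
#' the critical regime of Boolean network dynamics. Invariant under node
#' reordering and under replacing rules by isomorphic ones.
#'
#' @param model a [boolean_network()].
#' @export
network_average_sensitivity <- function(model) {
  if (length(model$rules) == 0L) stop("empty model")
  mean(vapply(model$rules, average_sensitivity, numeric(1)))
}

#' Sample a random rule of a prescribed type
#'
#' NCF / RoF / non-NCF RoF rules are drawn uniformly by indexing the exact
#' catalog; the remaining types (EF, UF, CF, ECF, EUF, and unrestricted
#' `"random"`) are drawn by exact-uniform rejection from the uniform
#' function distribution. Rejection is capped: rare types at large k (e.g.
#' UF or CF beyond k = 4) exhaust the cap and error with guidance. Uses the
#' R session RNG; seed with [set.seed()].
#'
#' @param k number of inputs.
#' @param type type label, or `"random"` for the unrestricted ensemble.
#' @param max_attempts rejection cap.
#' @return a [truth_table()] whose [classify_bf()] profile has the type.
#' @export
sample_rule <- function(k, type = "random", max_attempts = 1e6) {
  if (type %in% c("NCF", "RoF", "nonNCF-RoF")) {
    cat_obj <- build_catalog(k, type)
    if (cat_obj$count == 0L) {
      stop("no ", type, " functions exist at k = ", k)
    }
    return(hex_to_tt(cat_obj$keys[sample.int(cat_obj$count, 1L)], k))
  }
  if (type == "random") {
    return(truth_table(stats::rbinom(2^k, 1L, 0.5), k))
  }
  for (i in seq_len(max_attempts)) {
    tt <- truth_table(stats::rbinom(2^k, 1L, 0.5), k)
    if (isTRUE(type_flag(tt, type))) return(tt)
  }
  stop("rejection sampling cap reached for type ", type, " at k = ", k,
       "; this type is too rare here - use a catalog-backed type")
}

#' Distribution of network average sensitivities under type-constrained rules
#'
#' Re-implements the wiring-preserving randomization: for every model and
#' replicate, each node's rule is resampled from the prescribed type at the
#' node's in-degree and the network average sensitivity is recorded. The
#' type `"biological"` keeps the models' own rules (one value per model).
#'
#' @param models list of [boolean_network()] objects.
#' @param type type label for [sample_rule()], or `"biological"`.
#' @param replicates resamplings per model.
#' @param seed optional RNG seed.
#' @return a `sensitivity_distribution`: list with `values`, `type`,
#'   `mean`, and `ci` (empirical 2.5/97.5 percentiles).
#' @export
type_sensitivity_distribution <- function(models, type, replicates = 100L,
                                          seed = NULL) {
  if (length(models) == 0L) stop("need at least one model")
  if (!is.null(seed)) set.seed(seed)
  values <- if (type == "biological") {
    vapply(models, network_average_sensitivity, numeric(1))
  } else {
    unlist(lapply(models, function(mod) {
      ks <- vapply(mod$rules, function(r) r$k, integer(1))
      vapply(seq_len(replicates), function(rep) {
        mean(vapply(ks, function(k) average_sensitivity(sample_rule(k, type)),
                    numeric(1)))
      }, numeric(1))
    }))
  }
  values <- unname(values)
  structure(list(values = values, type = type, mean = mean(values),
                 ci = stats::quantile(values, c(0.025, 0.975), names = FALSE)),
            class = "sensitivity_distribution")
}

#' @export
print.sensitivity_distribution <- function(x, ...) {
  cat(sprintf(
    "sensitivity_distribution (%s): n=%d mean=%.3f 95%% interval [%.3f, %.3f]\n",
    x$type, length(x$values), x$mean, x$ci[1L], x$ci[2L]))
  invisible(x)
}

#' Fraction of a distribution outside a reference 95% interval
#'
#' The reference interval is the empirical central `level` interval
#' (percentiles by linear interpolation between order statistics); returns
#' the fraction of `dist` falling strictly outside it. Identical
#' distributions give about 1 - level.
#'
#' @param dist,reference_dist numeric vectors or `sensitivity_distribution`
#'   objects.
#' @param level central coverage of the reference interval.
#' @export
ci_overlap <- function(dist, reference_dist, level = 0.95) {
  v <- if (inherits(dist, "sensitivity_distribution")) dist$values else dist
  r <- if (inherits(reference_dist, "sensitivity_distribution")) {
    reference_dist$values
  } else reference_dist
  if (length(v) == 0L || length(r) == 0L) stop("empty distribution")
  a <- (1 - level) / 2
  q <- stats::quantile(r, c(a, 1 - a), names = FALSE, type = 7)
  mean(v < q[1L] | v > q[2L])
}
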