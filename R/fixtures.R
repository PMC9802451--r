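#' Specification for a synthetic model collection
#'
#' The generator emulates the shape of curated model collections: a set of
#' small Boolean networks whose in-degree histogram decays with k (most
#' rules have 1-2 inputs, large in-degrees are rare) and whose rules are
#' dominated by nested canalyzing logic, with a minority of other
#' biologically meaningful types and a pinch of unconstrained random rules.
#' Defaults: in-degree probabilities proportional to 2^-k up to `k_max`
#' (geometric decay), and a rule-type mixture of 85% NCF, 5% RoF, 5% EF and
#' 5% uniform-random.
#'
#' @param n_models number of models to generate.
#' @param nodes_range integer range (min, max) of nodes per model.
#' @param k_max largest in-degree.
#' @param indegree_probs probability over in-degrees `1..k_max`.
#' @param type_mixture named probabilities over rule types understood by
#'   [sample_rule()] (`"random"` for the unrestricted ensemble).
#' @param seed RNG seed; generation is bit-for-bit reproducible.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_models = 20L,
                         nodes_range = c(8L, 15L),
                         k_max = 6L,
                         indegree_probs = NULL,
                         type_mixture = c(NCF = 0.85, RoF = 0.05,
                                          EF = 0.05, random = 0.05),
                         seed = 1L) {
  if (is.null(indegree_probs)) {
    indegree_probs <- 2^-(1:k_max)
    indegree_probs <- indegree_probs / sum(indegree_probs)
  }
  if (length(indegree_probs) != k_max) {
    stop("indegree_probs must have length k_max")
  }
  if (abs(sum(indegree_probs) - 1) > 1e-9) {
    stop("indegree_probs must sum to 1")
  }
  if (abs(sum(type_mixture) - 1) > 1e-9 || is.null(names(type_mixture))) {
    stop("type_mixture must be a named vector summing to 1")
  }
  structure(list(n_models = as.integer(n_models),
                 nodes_range = as.integer(nodes_range),
                 k_max = as.integer(k_max),
                 indegree_probs = indegree_probs,
                 type_mixture = type_mixture,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic collection of Boolean network models
#'
#' Draws `n_models` networks according to a [fixture_spec()]: node counts
#' uniform on `nodes_range`, per-node in-degree from `indegree_probs`,
#' regulators sampled without replacement from the model's nodes (self-loops
#' allowed), and each rule drawn by [sample_rule()] from the type assigned
#' by `type_mixture`. Re-running with the same spec reproduces the
#' collection exactly.
#'
#' @param spec a [fixture_spec()].
#' @param dir optional directory: one rules TSV per model is written there.
#' @return a [reference_dataset()] with an extra `type` column recording the
#'   mixture component each rule was drawn from.
#' @export
generate_collection <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  recs <- list()
  for (mi in seq_len(spec$n_models)) {
    model_id <- sprintf("model%02d", mi)
    n_nodes <- sample(spec$nodes_range[1L]:spec$nodes_range[2L], 1L)
    nodes <- sprintf("g%02d", seq_len(n_nodes))
    for (ni in seq_len(n_nodes)) {
      k <- sample.int(spec$k_max, 1L, prob = spec$indegree_probs)
      k <- min(k, n_nodes)
      regs <- sample(nodes, k)
      type <- sample(names(spec$type_mixture), 1L,
                     prob = spec$type_mixture)
      tt <- sample_rule(k, type)
      recs[[length(recs) + 1L]] <- data.frame(
        model_id = model_id, node_id = nodes[ni],
        regulators = paste(regs, collapse = ","),
        output_bits = tt_to_string(tt), type = type)
    }
  }
  ds <- reference_dataset(do.call(rbind, recs))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (id in unique(ds$model_id)) {
      write_rules_tsv(ds[ds$model_id == id, , drop = FALSE],
                      file.path(dir, paste0(id, ".tsv")))
    }
  }
  ds
}
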