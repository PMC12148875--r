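# Decomposable BIC family scores for discrete data.
#
# Convention: score = logL - (d/2) * log(n), higher is better, with
# d = (r_child - 1) * prod(r_parents) free parameters per family. Terms
# with N_jk = 0 contribute 0 (the 0 * log 0 = 0 convention); parent
# configurations never observed contribute nothing to either term of the
# likelihood (their parameters are still counted by the penalty, as is
# standard for the dimension of the family).

#' BIC score of one node family
#'
#' `sum_jk N_jk * log(N_jk / N_j) - (d/2) * log(n)` over parent
#' configurations j and child levels k, with
#' `d = (r_child - 1) * prod(r_parents)`.
#'
#' @param data A [categorical_dataset()].
#' @param child Child variable name.
#' @param parents Character vector of parent names (may be empty).
#' @return Scalar score (higher is better).
#' @export
family_bic_score <- function(data, child, parents = character()) {
  schema <- dataset_schema(data)
  nm <- schema_names(schema)
  stopifnot(child %in% nm, all(parents %in% nm), !(child %in% parents))
  n <- nrow(data)
  if (n == 0L) stop("empty dataset", call. = FALSE)
  idx <- dataset_indices(data)
  family_bic_from_indices(idx, schema, child, sort(parents), n)
}

family_bic_from_indices <- function(idx, schema, child, parents, n) {
  sizes <- vapply(parents, n_levels, 1L, schema = schema)
  r <- n_levels(schema, child)
  j <- parent_config_index(idx[, parents, drop = FALSE], sizes)
  ncfg <- prod(c(1L, sizes))
  counts <- tabulate((idx[, child] - 1L) * ncfg + j, nbins = ncfg * r)
  counts <- matrix(counts, nrow = ncfg, ncol = r)
  nj <- rowSums(counts)
  pos <- counts > 0
  ll <- sum(counts[pos] * log(counts[pos] / nj[row(counts)[pos]]))
  d <- (r - 1) * ncfg
  ll - d / 2 * log(n)
}

#' BIC score of a whole network
#'
#' Sum of [family_bic_score()] over all nodes with their DAG parents
#' (score decomposability).
#'
#' @param data A [categorical_dataset()].
#' @param g A valid `bn_dag` over the dataset's variables.
#' @return Scalar score.
#' @export
network_bic_score <- function(data, g) {
  schema <- dataset_schema(data)
  check_dag_over(g, schema)
  idx <- dataset_indices(data)
  n <- nrow(data)
  sum(vapply(g$nodes, function(v) {
    family_bic_from_indices(idx, schema, v, parents(g, v), n)
  }, 0))
}
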