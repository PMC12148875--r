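# Conditional probability tables and the fitted-network container.
#
# Parent configuration indexing convention (fixed package-wide): a node's
# parents are sorted lexicographically; configuration rows enumerate parent
# levels with the LAST parent's level index varying fastest. Row 1 is all
# parents at level 1.

# Vectorized row index from a matrix of 1-based parent level indices
# (columns in sorted-parent order) given the parents' level counts.
parent_config_index <- function(idx, sizes) {
  if (length(sizes) == 0L) return(rep.int(1L, NROW(idx)))
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = length(sizes))
  out <- idx[, 1L] - 1L
  if (length(sizes) > 1L) {
    for (j in 2L:length(sizes)) out <- out * sizes[j] + (idx[, j] - 1L)
  }
  as.integer(out) + 1L
}

# All parent configurations as a matrix of level indices, one row per
# configuration in package order (last parent fastest).
parent_config_grid <- function(sizes) {
  if (length(sizes) == 0L) return(matrix(integer(), nrow = 1L, ncol = 0L))
  g <- as.matrix(rev(expand.grid(rev(lapply(sizes, seq_len)))))
  colnames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}

# Label a configuration row as "parent=level, ..." for messages/JSON.
config_label <- function(schema, pars, row) {
  if (!length(pars)) return("(root)")
  paste(vapply(seq_along(pars), function(j) {
    paste0(pars[j], "=", schema[[pars[j]]]$levels[row[j]])
  }, ""), collapse = ",")
}

new_bayes_net <- function(dag, schema, cpts) {
  structure(list(dag = dag, schema = schema, cpts = cpts),
            class = "bayes_net")
}

#' @export
print.bayes_net <- function(x, ...) {
  nflag <- sum(vapply(x$cpts, function(ct) sum(ct$unobserved), 0L))
  cat(sprintf("<bayes_net> %d nodes, %d arcs%s\n",
              length(x$dag$nodes), nrow(x$dag$arcs),
              if (nflag) sprintf(" (%d unobserved CPT rows)", nflag) else ""))
  invisible(x)
}

#' Fit conditional probability tables by maximum likelihood
#'
#' For every node, the CPT entry for child level k under parent
#' configuration j is `(N_jk + pseudocount) / (N_j + pseudocount * r)`,
#' with `r` the node's level count. The default `pseudocount = 0` is pure
#' MLE. Parent configurations never observed in the data cannot be
#' estimated; under `pseudocount = 0` such rows are returned uniform and
#' flagged `unobserved` (with a warning), so downstream inference stays
#' total while reports can surface the flag.
#'
#' @param data A [categorical_dataset()].
#' @param g A valid `bn_dag` over the dataset's variables.
#' @param pseudocount Non-negative additive smoothing count (default 0).
#' @return A `bayes_net`: the DAG, the schema, and per-node CPTs. Each CPT
#'   is a list with `parents` (sorted), `prob` (configurations x levels
#'   matrix, rows summing to 1) and `unobserved` (logical per row).
#' @export
fit_mle_cpts <- function(data, g, pseudocount = 0) {
  schema <- dataset_schema(data)
  check_dag_over(g, schema)
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1L,
            pseudocount >= 0)
  idx <- dataset_indices(data)
  cpts <- lapply(g$nodes, function(v) {
    pars <- parents(g, v)
    sizes <- vapply(pars, n_levels, 1L, schema = schema)
    r <- n_levels(schema, v)
    ncfg <- prod(c(1L, sizes))
    j <- parent_config_index(idx[, pars, drop = FALSE], sizes)
    counts <- matrix(0, nrow = ncfg, ncol = r)
    tb <- table(factor(j, levels = seq_len(ncfg)),
                factor(idx[, v], levels = seq_len(r)))
    counts[] <- as.numeric(tb)
    nj <- rowSums(counts)
    unobserved <- nj == 0 & pseudocount == 0
    prob <- (counts + pseudocount) / (nj + pseudocount * r)
    prob[unobserved, ] <- 1 / r
    list(parents = pars, prob = prob, unobserved = unobserved,
         counts = counts)
  })
  names(cpts) <- g$nodes
  nflag <- sum(vapply(cpts, function(ct) sum(ct$unobserved), 0L))
  if (nflag > 0L) {
    warning(sprintf(
      "%d parent configuration(s) unobserved; returned uniform and flagged",
      nflag), call. = FALSE)
  }
  new_bayes_net(g, schema, cpts)
}

check_dag_over <- function(g, schema) {
  stopifnot(inherits(g, "bn_dag"))
  nm <- schema_names(schema)
  if (!setequal(g$nodes, nm)) {
    stop("DAG nodes do not match dataset variables", call. = FALSE)
  }
  v <- validate_dag(g)
  if (!v$valid) stop(v$diagnostic, call. = FALSE)
  invisible(TRUE)
}

#' Log-likelihood of a dataset under a fitted network
#'
#' Sum over records and nodes of the log CPT entry of the observed child
#' level given the observed parent levels. Returns `-Inf` if a required
#' entry is zero. Evaluating a record that needs an unobserved-flagged row
#' is an error under pure MLE semantics: the model assigns it no estimated
#' probability.
#'
#' @param data A [categorical_dataset()].
#' @param net A `bayes_net` from [fit_mle_cpts()] or the generator.
#' @return Scalar log-likelihood.
#' @export
loglik <- function(data, net) {
  stopifnot(inherits(net, "bayes_net"))
  schema <- dataset_schema(data)
  if (!identical(schema_names(schema), schema_names(net$schema))) {
    stop("dataset schema does not match network schema", call. = FALSE)
  }
  idx <- dataset_indices(data)
  total <- 0
  for (v in net$dag$nodes) {
    ct <- net$cpts[[v]]
    sizes <- vapply(ct$parents, n_levels, 1L, schema = schema)
    j <- parent_config_index(idx[, ct$parents, drop = FALSE], sizes)
    if (any(ct$unobserved[j])) {
      stop(sprintf(
        "record requires unobserved CPT row of node '%s'; refit with a pseudocount",
        v), call. = FALSE)
    }
    p <- ct$prob[cbind(j, idx[, v])]
    if (any(p == 0)) return(-Inf)
    total <- total + sum(log(p))
  }
  total
}

cpt_row_check <- function(net, tol = 1e-9) {
  for (v in names(net$cpts)) {
    s <- rowSums(net$cpts[[v]]$prob)
    if (any(abs(s - 1) > tol)) {
      stop(sprintf("CPT rows of '%s' do not sum to 1", v), call. = FALSE)
    }
  }
  invisible(TRUE)
}
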