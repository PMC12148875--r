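# Shared fixtures and independent oracles. Everything here deliberately
# avoids the package's vectorized code paths: oracles recount, re-enumerate
# or brute-force with plain loops so agreement is meaningful.

binary_schema <- function(names) {
  out <- lapply(names, function(v) variable_spec(v, c("no", "yes"), "pain"))
  names(out) <- names
  out
}

toy_dataset <- function(cols, schema = NULL) {
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  if (is.null(schema)) schema <- binary_schema(names(df))
  categorical_dataset(df, schema)
}

# Assemble a bayes_net by hand from a named list of CPT matrices
# (config rows x child levels; package configuration order).
make_net <- function(g, schema, prob_list) {
  cpts <- lapply(g$nodes, function(v) {
    pr <- prob_list[[v]]
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1L)
    list(parents = painbn::parents(g, v), prob = pr,
         unobserved = rep(FALSE, nrow(pr)))
  })
  names(cpts) <- g$nodes
  structure(list(dag = g, schema = schema, cpts = cpts),
            class = "bayes_net")
}

# Random DAG over given nodes: each lexicographically ordered pair gets an
# arc with probability p (always acyclic by construction), then arcs are
# randomly reoriented where legal via the package constructor checks.
random_dag <- function(nodes, p = 0.4) {
  arcs <- NULL
  ord <- sample(nodes)
  for (i in seq_along(ord)) {
    for (j in seq_along(ord)) {
      if (i < j && stats::runif(1) < p) arcs <- rbind(arcs, ord[c(i, j)])
    }
  }
  dag(nodes, arcs)
}

# Random CPTs (binary nodes) for a DAG.
random_net <- function(g, schema = binary_schema(g$nodes)) {
  prob_list <- lapply(g$nodes, function(v) {
    np <- length(painbn::parents(g, v))
    ncfg <- 2L^np
    py <- stats::runif(ncfg, 0.05, 0.95)
    unname(cbind(1 - py, py))
  })
  names(prob_list) <- g$nodes
  make_net(g, schema, prob_list)
}

# ---- oracles ---------------------------------------------------------------

# Joint probability of one full assignment by naive per-node lookup: walks
# the parent configuration grid row by row instead of using index
# arithmetic.
oracle_joint <- function(net, assignment) {
  schema <- net$schema
  p <- 1
  for (v in net$dag$nodes) {
    ct <- net$cpts[[v]]
    pars <- ct$parents
    sizes <- vapply(pars, function(x) length(schema[[x]]$levels), 1L)
    row <- 1L
    if (length(pars)) {
      grid <- expand.grid(rev(lapply(sizes, seq_len)))
      grid <- as.matrix(grid)[, rev(seq_along(pars)), drop = FALSE]
      want <- vapply(pars, function(x) {
        match(assignment[[x]], schema[[x]]$levels)
      }, 1L)
      row <- which(apply(grid, 1L, function(r) all(r == want)))
    }
    k <- match(assignment[[v]], schema[[v]]$levels)
    p <- p * as.numeric(ct$prob[row, k])
  }
  p
}

# Brute-force conditional query: enumerate every full assignment with
# nested expand.grid over level labels and sum oracle_joint terms.
oracle_query <- function(net, target, evidence = character()) {
  schema <- net$schema
  nodes <- net$dag$nodes
  lv <- lapply(nodes, function(v) schema[[v]]$levels)
  names(lv) <- nodes
  grid <- expand.grid(lv, stringsAsFactors = FALSE)
  num <- 0; den <- 0
  for (i in seq_len(nrow(grid))) {
    asg <- as.character(grid[i, ]); names(asg) <- nodes
    if (all(asg[names(evidence)] == evidence)) {
      pj <- oracle_joint(net, asg)
      den <- den + pj
      if (asg[[names(target)]] == target[[1L]]) num <- num + pj
    }
  }
  num / den
}

# Independent family log-likelihood + BIC: counts via split() on pasted
# parent labels, not index arithmetic.
oracle_family_bic <- function(data, child, parents) {
  n <- nrow(data)
  key <- if (length(parents)) {
    do.call(paste, c(lapply(parents, function(p) as.character(data[[p]])),
                     sep = "|"))
  } else rep("all", n)
  ll <- 0
  for (grp in split(as.character(data[[child]]), key)) {
    nj <- length(grp)
    for (cnt in table(grp)) ll <- ll + cnt * log(cnt / nj)
  }
  schema <- attr(data, "schema")
  r <- length(schema[[child]]$levels)
  q <- prod(vapply(parents, function(p) length(schema[[p]]$levels), 1L),
            1L)
  ll - (r - 1) * q / 2 * log(n)
}

# Is `ord` a valid topological order of g? (direct definition)
is_topo_order <- function(g, ord) {
  pos <- match(g$nodes, ord)
  names(pos) <- g$nodes
  if (anyNA(pos)) return(FALSE)
  !nrow(g$arcs) || all(pos[g$arcs[, 1L]] < pos[g$arcs[, 2L]])
}

# Acyclicity by brute force: try all node permutations (small graphs only).
oracle_acyclic <- function(g) {
  stopifnot(length(g$nodes) <= 6L)
  perms <- function(x) {
    if (length(x) <= 1L) return(list(x))
    out <- list()
    for (i in seq_along(x)) {
      for (rest in perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
    }
    out
  }
  any(vapply(perms(g$nodes), function(p) is_topo_order(g, p), TRUE))
}

default_truth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_default_truth_network()
    cache
  }
})
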