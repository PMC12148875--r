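# Exact inference on a fitted discrete network. The reference path is full
# enumeration (the pain network has ~6k joint states); a variable-elimination
# fast path gives identical answers and is cross-checked in the test suite.

#' Joint probability of a full assignment
#'
#' Chain-rule product of CPT entries:
#' `prod over nodes of P(node = assigned | parents = assigned)`.
#'
#' @param net A `bayes_net`.
#' @param assignment Named character vector mapping every node to a level
#'   label.
#' @return Probability. If the evaluation touches an unobserved-flagged CPT
#'   row, a warning is issued.
#' @export
joint_probability <- function(net, assignment) {
  stopifnot(inherits(net, "bayes_net"))
  schema <- net$schema
  nodes <- net$dag$nodes
  if (!setequal(names(assignment), nodes)) {
    stop("assignment must cover every node exactly once", call. = FALSE)
  }
  lvl <- vapply(nodes, function(v) {
    k <- match(assignment[[v]], schema[[v]]$levels)
    if (is.na(k)) stop(sprintf("invalid level '%s' for node '%s'",
                               assignment[[v]], v), call. = FALSE)
    k
  }, 1L)
  p <- 1
  flagged <- FALSE
  for (v in nodes) {
    ct <- net$cpts[[v]]
    sizes <- vapply(ct$parents, n_levels, 1L, schema = schema)
    j <- parent_config_index(matrix(lvl[ct$parents], nrow = 1L), sizes)
    if (ct$unobserved[j]) flagged <- TRUE
    p <- p * ct$prob[j, lvl[[v]]]
  }
  if (flagged) warning("assignment touches an unobserved CPT row",
                       call. = FALSE)
  p
}

# Full joint as (grid of level indices, probability vector), computed by
# vectorized chain-rule over the enumeration grid. Grid columns follow
# dag$nodes (sorted) order; rows enumerate levels with the last column
# varying fastest.
full_joint <- function(net) {
  schema <- net$schema
  nodes <- net$dag$nodes
  sizes <- vapply(nodes, n_levels, 1L, schema = schema)
  grid <- parent_config_grid(sizes)
  colnames(grid) <- nodes
  pr <- rep(1, nrow(grid))
  for (v in nodes) {
    ct <- net$cpts[[v]]
    psz <- vapply(ct$parents, n_levels, 1L, schema = schema)
    j <- parent_config_index(grid[, ct$parents, drop = FALSE], psz)
    pr <- pr * ct$prob[cbind(j, grid[, v])]
  }
  list(grid = grid, prob = pr)
}

#' Exact conditional-probability query
#'
#' Computes `P(target node = target level | evidence)` on a fitted network,
#' either by summing the full joint over assignments consistent with the
#' evidence (method `"enumeration"`, the reference path) or by variable
#' elimination over CPT factors (method `"ve"`). Both are exact and agree
#' to numerical precision.
#'
#' @param net A `bayes_net`.
#' @param target Named character of length 1, e.g. `c(knee = "yes")`.
#' @param evidence Named character vector of observed nodes and levels
#'   (possibly empty). The target node may not appear in the evidence.
#' @param method `"enumeration"` or `"ve"`.
#' @return Probability in `[0, 1]`. Error if `P(evidence) = 0`.
#' @examples
#' net <- build_default_truth_network()
#' query_conditional(net, c(neck = "yes"), c(headache = "yes"))
#' @export
query_conditional <- function(net, target, evidence = character(),
                              method = c("enumeration", "ve")) {
  method <- match.arg(method)
  stopifnot(inherits(net, "bayes_net"))
  schema <- net$schema
  nodes <- net$dag$nodes
  if (length(target) != 1L || is.null(names(target))) {
    stop("target must be one named node=level pair", call. = FALSE)
  }
  tn <- names(target)
  if (!(tn %in% nodes)) stop("unknown target node: ", tn, call. = FALSE)
  if (tn %in% names(evidence)) {
    stop("target node may not appear in the evidence", call. = FALSE)
  }
  check_levels <- function(x) {
    for (v in names(x)) {
      if (!(v %in% nodes)) stop("unknown node: ", v, call. = FALSE)
      if (!(x[[v]] %in% schema[[v]]$levels)) {
        stop(sprintf("invalid level '%s' for node '%s'", x[[v]], v),
             call. = FALSE)
      }
    }
  }
  check_levels(target); check_levels(evidence)

  if (method == "enumeration") {
    fj <- full_joint(net)
    keep <- rep(TRUE, length(fj$prob))
    for (v in names(evidence)) {
      keep <- keep & fj$grid[, v] == match(evidence[[v]], schema[[v]]$levels)
    }
    pe <- sum(fj$prob[keep])
    if (pe <= 0) stop("evidence has probability zero", call. = FALSE)
    kt <- keep & fj$grid[, tn] == match(target[[1L]], schema[[tn]]$levels)
    sum(fj$prob[kt]) / pe
  } else {
    num <- ve_marginal(net, tn, evidence)
    pe <- sum(num)
    if (pe <= 0) stop("evidence has probability zero", call. = FALSE)
    num[[match(target[[1L]], schema[[tn]]$levels)]] / pe
  }
}

# Variable elimination: returns the unnormalized distribution over the
# query node's levels given the evidence. Factors are dense arrays over
# subsets of nodes, stored as (vars, table over package config order).
ve_marginal <- function(net, qnode, evidence) {
  schema <- net$schema
  nodes <- net$dag$nodes
  sizes <- vapply(nodes, n_levels, 1L, schema = schema)
  names(sizes) <- nodes
  ev_idx <- vapply(names(evidence), function(v) {
    match(evidence[[v]], schema[[v]]$levels)
  }, 1L)

  factors <- lapply(nodes, function(v) {
    ct <- net$cpts[[v]]
    vars <- c(ct$parents, v)  # config order: parents then child fastest
    tab <- as.vector(t(ct$prob))  # child level varies fastest
    f <- list(vars = vars, tab = tab)
    reduce_factor(f, ev_idx, sizes)
  })
  elim <- setdiff(nodes, c(qnode, names(evidence)))
  for (v in elim) {
    touch <- vapply(factors, function(f) v %in% f$vars, TRUE)
    merged <- Reduce(function(a, b) factor_product(a, b, sizes),
                     factors[touch])
    factors <- c(factors[!touch],
                 list(factor_marginalize(merged, v, sizes)))
  }
  res <- Reduce(function(a, b) factor_product(a, b, sizes), factors)
  # res may still mention evidence vars reduced to scalars; vars are qnode
  # or empty. Marginalize anything that is not the query node (shouldn't
  # happen, defensive) and return the distribution over qnode levels.
  for (v in setdiff(res$vars, qnode)) res <- factor_marginalize(res, v, sizes)
  if (!length(res$vars)) return(rep(res$tab, sizes[[qnode]]) / sizes[[qnode]])
  res$tab
}

# Restrict a factor to the evidence: select matching slices, drop the vars.
reduce_factor <- function(f, ev_idx, sizes) {
  hit <- intersect(f$vars, names(ev_idx))
  if (!length(hit)) return(f)
  sz <- sizes[f$vars]
  grid <- parent_config_grid(sz)
  keep <- rep(TRUE, nrow(grid))
  for (v in hit) keep <- keep & grid[, match(v, f$vars)] == ev_idx[[v]]
  newvars <- setdiff(f$vars, hit)
  if (!length(newvars)) return(list(vars = character(), tab = sum(f$tab[keep])))
  sub <- grid[keep, match(newvars, f$vars), drop = FALSE]
  ord <- order(parent_config_index(sub, sizes[newvars]))
  list(vars = newvars, tab = f$tab[keep][ord])
}

factor_product <- function(a, b, sizes) {
  vars <- union(a$vars, b$vars)
  if (!length(vars)) return(list(vars = character(), tab = a$tab * b$tab))
  sz <- sizes[vars]
  grid <- parent_config_grid(sz)
  val <- rep(1, nrow(grid))
  for (f in list(a, b)) {
    if (!length(f$vars)) { val <- val * f$tab; next }
    j <- parent_config_index(grid[, match(f$vars, vars), drop = FALSE],
                             sizes[f$vars])
    val <- val * f$tab[j]
  }
  list(vars = vars, tab = val)
}

factor_marginalize <- function(f, v, sizes) {
  if (!(v %in% f$vars)) return(f)
  newvars <- setdiff(f$vars, v)
  if (!length(newvars)) return(list(vars = character(), tab = sum(f$tab)))
  sz <- sizes[f$vars]
  grid <- parent_config_grid(sz)
  j <- parent_config_index(grid[, match(newvars, f$vars), drop = FALSE],
                           sizes[newvars])
  list(vars = newvars,
       tab = as.vector(tapply(f$tab, factor(j, levels = seq_len(max(j))),
                              sum)))
}
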