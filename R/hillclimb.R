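# Greedy score-based structure search: single-arc additions, deletions and
# reversals from the empty graph, under an arc blacklist.

#' Hill-climbing structure learning with BIC
#'
#' Starts from the empty graph and repeatedly applies the single-arc move
#' (add, delete, or reverse) with the largest strictly positive score gain,
#' among moves that keep the graph acyclic and contain no blacklisted arc.
#' Stops at a local optimum (no move improves the score by more than
#' `tolerance`). Family scores are cached per (child, parent-set) so each
#' move only rescores the one or two families it touches.
#'
#' Determinism: candidate moves are enumerated in a fixed order — move type
#' add < delete < reverse, then (parent, child) lexicographic — and exact
#' score ties are resolved by that order, so the search is reproducible.
#'
#' Optional random restarts (`restarts > 0`) perturb the local optimum with
#' `perturb` random arc additions/deletions (seeded) and climb again,
#' keeping the best-scoring result; the default of no restarts reflects
#' plain greedy search.
#'
#' @param data A [categorical_dataset()].
#' @param constraints An [arc_constraints()] blacklist
#'   (default: none; use [demographic_blacklist()] for survey analyses).
#' @param tolerance Minimal score improvement to accept a move
#'   (default 1e-9, guarding floating-point no-ops).
#' @param restarts Number of random restarts (default 0).
#' @param perturb Arc perturbations per restart (default 4).
#' @param seed RNG seed used only when `restarts > 0`.
#' @return A `search_trace`: list with `dag` (final `bn_dag`), `score`
#'   (final network BIC), and `trace` (data frame of accepted moves with
#'   columns `move`, `from`, `to`, `score`).
#' @export
hill_climb <- function(data, constraints = arc_constraints(),
                       tolerance = 1e-9, restarts = 0L, perturb = 4L,
                       seed = 1L) {
  schema <- dataset_schema(data)
  stopifnot(inherits(constraints, "arc_constraints"))
  if (nrow(data) == 0L) stop("empty dataset", call. = FALSE)
  nodes <- sort(schema_names(schema))
  idx <- dataset_indices(data)
  n <- nrow(data)
  cache <- new.env(parent = emptyenv())
  fam <- function(child, pars) {
    key <- paste0(child, "|", paste(pars, collapse = ","))
    got <- cache[[key]]
    if (!is.null(got)) return(got)
    val <- family_bic_from_indices(idx, schema, child, pars, n)
    cache[[key]] <- val
    val
  }
  blacklisted <- function(from, to) {
    bl <- constraints$blacklist
    nrow(bl) > 0L && any(bl[, 1L] == from & bl[, 2L] == to)
  }

  climb <- function(g, trace) {
    fam_score <- stats::setNames(
      vapply(nodes, function(v) fam(v, parents(g, v)), 0), nodes)
    score <- sum(fam_score)
    repeat {
      best <- NULL  # list(move, from, to, gain, new_fams)
      consider <- function(move, from, to, gain, new_fams) {
        if (gain > tolerance &&
            (is.null(best) || gain > best$gain)) {
          best <<- list(move = move, from = from, to = to, gain = gain,
                        new_fams = new_fams)
        }
      }
      # additions
      for (from in nodes) for (to in nodes) {
        if (from == to || has_arc(g, from, to) || blacklisted(from, to)) next
        if (has_directed_path(g, to, from)) next  # would create a cycle
        s_new <- fam(to, sort(c(parents(g, to), from)))
        consider("add", from, to, s_new - fam_score[[to]],
                 stats::setNames(list(s_new), to))
      }
      # deletions
      if (nrow(g$arcs)) for (k in seq_len(nrow(g$arcs))) {
        from <- g$arcs[k, 1L]; to <- g$arcs[k, 2L]
        s_new <- fam(to, setdiff(parents(g, to), from))
        consider("delete", from, to, s_new - fam_score[[to]],
                 stats::setNames(list(s_new), to))
      }
      # reversals
      if (nrow(g$arcs)) for (k in seq_len(nrow(g$arcs))) {
        from <- g$arcs[k, 1L]; to <- g$arcs[k, 2L]
        if (blacklisted(to, from)) next
        g2 <- drop_arc(g, from, to)
        if (has_directed_path(g2, from, to)) next  # reversal closes a cycle
        s_to <- fam(to, setdiff(parents(g, to), from))
        s_from <- fam(from, sort(c(parents(g, from), to)))
        gain <- (s_to - fam_score[[to]]) + (s_from - fam_score[[from]])
        consider("reverse", from, to, gain,
                 stats::setNames(list(s_to, s_from), c(to, from)))
      }
      if (is.null(best)) break
      g <- switch(best$move,
        add = add_arc(g, best$from, best$to),
        delete = drop_arc(g, best$from, best$to),
        reverse = add_arc(drop_arc(g, best$from, best$to),
                          best$to, best$from))
      for (v in names(best$new_fams)) fam_score[[v]] <- best$new_fams[[v]]
      score <- sum(fam_score)
      trace <- rbind(trace, data.frame(
        move = best$move, from = best$from, to = best$to, score = score,
        stringsAsFactors = FALSE))
    }
    list(dag = g, score = score, trace = trace)
  }

  empty_trace <- data.frame(move = character(), from = character(),
                            to = character(), score = numeric(),
                            stringsAsFactors = FALSE)
  res <- climb(dag(nodes), empty_trace)
  if (restarts > 0L) {
    set.seed(seed)
    for (r in seq_len(restarts)) {
      g <- perturb_dag(res$dag, perturb, constraints)
      cand <- climb(g, empty_trace)
      if (cand$score > res$score + tolerance) res <- cand
    }
  }
  structure(res, class = "search_trace")
}

#' @export
print.search_trace <- function(x, ...) {
  cat(sprintf("<search_trace> %d accepted moves, final score %.4f, %d arcs\n",
              nrow(x$trace), x$score, nrow(x$dag$arcs)))
  invisible(x)
}

# Random add/delete perturbations that respect acyclicity + blacklist.
perturb_dag <- function(g, k, constraints) {
  nodes <- g$nodes
  for (i in seq_len(k)) {
    from <- sample(nodes, 1L)
    to <- sample(setdiff(nodes, from), 1L)
    if (has_arc(g, from, to)) {
      g <- drop_arc(g, from, to)
    } else {
      bl <- constraints$blacklist
      bad <- nrow(bl) > 0L && any(bl[, 1L] == from & bl[, 2L] == to)
      if (!bad && !has_directed_path(g, to, from)) g <- add_arc(g, from, to)
    }
  }
  g
}

#' Compare two DAGs structurally
#'
#' Adjacency (skeleton) recovery and structural Hamming distance of a
#' learned DAG against a reference.
#'
#' @param learned,truth `bn_dag` objects over the same nodes.
#' @return List with `tp`, `fp`, `fn` (skeleton adjacency counts),
#'   `adjacency_recall`, `adjacency_precision`, and `shd` (arcs to add,
#'   drop, or reverse to turn `learned` into `truth`).
#' @export
compare_dags <- function(learned, truth) {
  stopifnot(setequal(learned$nodes, truth$nodes))
  und <- function(g) {
    if (!nrow(g$arcs)) return(character())
    unique(paste(pmin(g$arcs[, 1L], g$arcs[, 2L]),
                 pmax(g$arcs[, 1L], g$arcs[, 2L]), sep = "\r"))
  }
  sl <- und(learned); st <- und(truth)
  dl <- arc_key(learned$arcs[, 1L], learned$arcs[, 2L])
  dt <- arc_key(truth$arcs[, 1L], truth$arcs[, 2L])
  tp <- length(intersect(sl, st))
  fp <- length(setdiff(sl, st))
  fn <- length(setdiff(st, sl))
  # skeleton edges present in both but oriented oppositely count once
  rev_ct <- sum(vapply(strsplit(intersect(sl, st), "\r"), function(p) {
    (arc_key(p[1L], p[2L]) %in% dl) != (arc_key(p[1L], p[2L]) %in% dt)
  }, TRUE))
  list(tp = tp, fp = fp, fn = fn,
       adjacency_recall = if (length(st)) tp / length(st) else NA_real_,
       adjacency_precision = if (length(sl)) tp / length(sl) else NA_real_,
       shd = fp + fn + rev_ct)
}
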