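#' Construct a directed graph over named nodes
#'
#' Arcs are given as a two-column matrix (or data frame) of
#' `(parent, child)` name pairs. Construction checks that arcs reference
#' declared nodes and rejects self-arcs and duplicates; acyclicity is a
#' separate check ([validate_dag()]) so that invalid candidates arising
#' during search can still be represented and diagnosed.
#'
#' @param nodes Character vector of unique node names.
#' @param arcs Two-column character matrix/data frame of (parent, child)
#'   pairs, or `NULL` for an empty graph.
#' @return An object of class `bn_dag` with elements `nodes` (sorted) and
#'   `arcs` (character matrix with columns `from`, `to`).
#' @export
dag <- function(nodes, arcs = NULL) {
  if (!is.character(nodes) || length(nodes) == 0L || anyDuplicated(nodes)) {
    stop("nodes must be unique non-empty character names", call. = FALSE)
  }
  if (is.null(arcs) || NROW(arcs) == 0L) {
    arcs <- matrix(character(), ncol = 2L)
  } else {
    arcs <- as.matrix(arcs)
    if (ncol(arcs) != 2L) stop("arcs must have two columns", call. = FALSE)
    storage.mode(arcs) <- "character"
  }
  colnames(arcs) <- c("from", "to")
  undeclared <- setdiff(unique(c(arcs)), nodes)
  if (length(undeclared)) {
    stop("arc references undeclared node(s): ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  }
  if (any(arcs[, 1L] == arcs[, 2L])) stop("self-arcs are not allowed",
                                          call. = FALSE)
  key <- paste(arcs[, 1L], arcs[, 2L], sep = "\r")
  if (anyDuplicated(key)) stop("duplicate arcs are not allowed",
                               call. = FALSE)
  if (nrow(arcs) > 1L) arcs <- arcs[order(arcs[, 1L], arcs[, 2L]), ,
                                    drop = FALSE]
  structure(list(nodes = sort(nodes), arcs = arcs), class = "bn_dag")
}

#' @export
print.bn_dag <- function(x, ...) {
  cat(sprintf("<bn_dag> %d nodes, %d arcs\n", length(x$nodes), nrow(x$arcs)))
  if (nrow(x$arcs)) {
    cat(paste0("  ", x$arcs[, 1L], " -> ", x$arcs[, 2L], collapse = "\n"),
        "\n")
  }
  invisible(x)
}

#' Parents of a node
#' @param g A `bn_dag`.
#' @param node Node name.
#' @return Character vector of parent names, sorted lexicographically.
#' @export
parents <- function(g, node) {
  unname(sort(g$arcs[g$arcs[, 2L] == node, 1L]))
}

#' Children of a node
#' @inheritParams parents
#' @return Character vector of child names, sorted lexicographically.
#' @export
children <- function(g, node) {
  unname(sort(g$arcs[g$arcs[, 1L] == node, 2L]))
}

#' Check a directed graph for DAG validity
#'
#' @param g A `bn_dag`.
#' @return A list with `valid` (logical) and `diagnostic` (string; names one
#'   offending cycle when invalid, empty otherwise).
#' @export
validate_dag <- function(g) {
  stopifnot(inherits(g, "bn_dag"))
  ord <- try(topological_order(g), silent = TRUE)
  if (!inherits(ord, "try-error")) {
    return(list(valid = TRUE, diagnostic = ""))
  }
  list(valid = FALSE, diagnostic = attr(ord, "condition")$message)
}

#' Topological order of a DAG
#'
#' Kahn's algorithm with a deterministic tie-break: among nodes whose
#' parents have all been emitted, the lexicographically smallest name is
#' emitted first. Every parent therefore precedes each of its children and
#' the output is reproducible across platforms.
#'
#' @param g A `bn_dag`.
#' @return Character vector of node names.
#' @export
topological_order <- function(g) {
  stopifnot(inherits(g, "bn_dag"))
  nodes <- g$nodes  # already sorted
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  if (nrow(g$arcs)) {
    tb <- table(g$arcs[, 2L])
    indeg[names(tb)] <- as.integer(tb)
  }
  out <- character(0)
  remaining <- nodes
  while (length(remaining)) {
    ready <- remaining[indeg[remaining] == 0L]
    if (!length(ready)) {
      cyc <- find_cycle(g, remaining)
      stop("graph is cyclic: ", paste(cyc, collapse = " -> "),
           call. = FALSE)
    }
    nxt <- ready[1L]  # lexicographic: 'remaining' keeps sorted order
    out <- c(out, nxt)
    remaining <- setdiff(remaining, nxt)
    ch <- g$arcs[g$arcs[, 1L] == nxt, 2L]
    if (length(ch)) indeg[ch] <- indeg[ch] - 1L
  }
  out
}

# Walk successors from an unresolved node until a repeat closes the cycle.
find_cycle <- function(g, remaining) {
  start <- remaining[1L]
  path <- start
  cur <- start
  repeat {
    nxt <- sort(g$arcs[g$arcs[, 1L] == cur & g$arcs[, 2L] %in% remaining,
                       2L])[1L]
    if (nxt %in% path) {
      return(c(path[which(path == nxt):length(path)], nxt))
    }
    path <- c(path, nxt)
    cur <- nxt
  }
}

# TRUE iff 'to' is reachable from 'from' along directed arcs.
has_directed_path <- function(g, from, to) {
  if (from == to) return(TRUE)
  frontier <- from
  seen <- character(0)
  while (length(frontier)) {
    nxt <- unique(g$arcs[g$arcs[, 1L] %in% frontier, 2L])
    if (to %in% nxt) return(TRUE)
    seen <- c(seen, frontier)
    frontier <- setdiff(nxt, seen)
  }
  FALSE
}

arc_key <- function(from, to) paste(from, to, sep = "\r")

has_arc <- function(g, from, to) {
  any(g$arcs[, 1L] == from & g$arcs[, 2L] == to)
}

add_arc <- function(g, from, to) {
  g$arcs <- rbind(g$arcs, c(from, to))
  ord <- order(g$arcs[, 1L], g$arcs[, 2L])
  g$arcs <- g$arcs[ord, , drop = FALSE]
  colnames(g$arcs) <- c("from", "to")
  g
}

drop_arc <- function(g, from, to) {
  keep <- !(g$arcs[, 1L] == from & g$arcs[, 2L] == to)
  g$arcs <- g$arcs[keep, , drop = FALSE]
  g
}

#' Arc constraints (blacklist) for constrained structure search
#'
#' @param blacklist Two-column character matrix/data frame of forbidden
#'   (parent, child) pairs.
#' @return An object of class `arc_constraints`.
#' @seealso [demographic_blacklist()] for the standard survey constraint set.
#' @export
arc_constraints <- function(blacklist = NULL) {
  if (is.null(blacklist) || NROW(blacklist) == 0L) {
    blacklist <- matrix(character(), ncol = 2L)
  } else {
    blacklist <- as.matrix(blacklist)
    storage.mode(blacklist) <- "character"
    if (ncol(blacklist) != 2L) stop("blacklist must have two columns",
                                    call. = FALSE)
    blacklist <- unique(blacklist)
  }
  colnames(blacklist) <- c("from", "to")
  structure(list(blacklist = blacklist), class = "arc_constraints")
}

#' Blacklist keeping demographic variables exogenous
#'
#' Builds the constraint set used throughout: no variable may point into a
#' demographic variable (pain cannot alter age or gender), and no arcs are
#' allowed between demographics in either direction.
#'
#' @param schema A schema as from [pain_schema()].
#' @return An [arc_constraints()] object.
#' @export
demographic_blacklist <- function(schema = pain_schema()) {
  schema <- schema_check(schema)
  nm <- schema_names(schema)
  demo <- nm[vapply(schema, `[[`, "", "role") == "demographic"]
  bl <- do.call(rbind, lapply(demo, function(d) {
    cbind(setdiff(nm, d), d)
  }))
  arc_constraints(bl)
}

#' Does a graph violate an arc blacklist?
#'
#' @param g A `bn_dag`.
#' @param constraints An [arc_constraints()] object.
#' @return `TRUE` iff any arc of `g` is blacklisted.
#' @export
violates_constraints <- function(g, constraints) {
  stopifnot(inherits(g, "bn_dag"), inherits(constraints, "arc_constraints"))
  if (!nrow(g$arcs) || !nrow(constraints$blacklist)) return(FALSE)
  any(arc_key(g$arcs[, 1L], g$arcs[, 2L]) %in%
        arc_key(constraints$blacklist[, 1L], constraints$blacklist[, 2L]))
}

#' The reference pain-network structure
#'
#' The 23-arc DAG over the 12 survey variables used as the generator's
#' ground truth: demographics point into headache, knee, hand and neck;
#' headache, hand, neck, back and foot propagate into downstream sites.
#'
#' @return A `bn_dag` over the [pain_schema()] variables.
#' @export
reference_dag <- function() {
  arcs <- rbind(
    c("age", "headache"), c("age", "knee"),
    c("gender", "headache"), c("gender", "hand"), c("gender", "neck"),
    c("headache", "neck"), c("headache", "hip"), c("headache", "stomach"),
    c("headache", "face"), c("headache", "back"),
    c("hip", "hand"),
    c("hand", "face"), c("hand", "foot"), c("hand", "all_body"),
    c("hand", "back"), c("hand", "neck"),
    c("neck", "back"), c("neck", "foot"), c("neck", "stomach"),
    c("back", "stomach"), c("back", "knee"), c("back", "all_body"),
    c("foot", "knee")
  )
  dag(schema_names(pain_schema()), arcs)
}
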