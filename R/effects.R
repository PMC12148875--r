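# Odds-ratio statistics: 2x2 contingency extraction, OR from conditional
# probabilities, Woolf confidence intervals from counts, and the
# relationship report over a learned DAG.

#' 2x2 contingency table for an (evidence, event) pair
#'
#' Cell layout: `a` = events with evidence, `b` = non-events with evidence,
#' `c` = events without evidence, `d` = non-events without evidence.
#' Multi-level evidence (the age group) is dichotomized level-vs-rest, so
#' e.g. evidence `(age, senior)` contrasts seniors against everyone else.
#'
#' @param data A [categorical_dataset()].
#' @param evidence,event Named character of length 1 (`c(node = level)`);
#'   the two nodes must be distinct. The event level is the "event
#'   present" level (for pain variables, `"yes"`).
#' @return A list of class `contingency_2x2` with integer fields
#'   `a`, `b`, `c`, `d` and the labels.
#' @export
contingency_2x2 <- function(data, evidence, event) {
  schema <- dataset_schema(data)
  ev_n <- names(evidence); et_n <- names(event)
  stopifnot(length(evidence) == 1L, length(event) == 1L,
            !is.null(ev_n), !is.null(et_n))
  if (ev_n == et_n) stop("evidence and event nodes must differ",
                         call. = FALSE)
  for (p in list(evidence, event)) {
    v <- names(p)
    if (!(v %in% schema_names(schema))) stop("unknown variable: ", v,
                                             call. = FALSE)
    if (!(p[[1L]] %in% schema[[v]]$levels)) {
      stop(sprintf("invalid level '%s' for '%s'", p[[1L]], v),
           call. = FALSE)
    }
  }
  if (nrow(data) == 0L) stop("empty dataset", call. = FALSE)
  e <- data[[ev_n]] == evidence[[1L]]
  y <- data[[et_n]] == event[[1L]]
  structure(list(a = sum(e & y), b = sum(e & !y),
                 c = sum(!e & y), d = sum(!e & !y),
                 evidence = evidence, event = event),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("<contingency_2x2> %s=%s vs %s=%s: a=%d b=%d c=%d d=%d\n",
              names(x$evidence), x$evidence[[1L]],
              names(x$event), x$event[[1L]], x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Odds ratio from two conditional probabilities
#'
#' `OR = (p1 / (1 - p1)) / (p2 / (1 - p2))` where `p1 = P(event |
#' evidence)` and `p2 = P(event | no evidence)`. Degenerate probabilities
#' (0 or 1) yield `Inf` or `0` with attribute `degenerate = TRUE` rather
#' than an error, so callers can flag the row.
#'
#' @param p1,p2 Probabilities in `[0, 1]`.
#' @return The odds ratio.
#' @examples
#' odds_ratio_from_probs(0.51138, 0.26739)  # ~2.867
#' @export
odds_ratio_from_probs <- function(p1, p2) {
  stopifnot(is.numeric(p1), is.numeric(p2),
            p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1)) {
    odds1 <- if (p1 == 1) Inf else p1 / (1 - p1)
    odds2 <- if (p2 == 1) Inf else p2 / (1 - p2)
    out <- if (is.infinite(odds1) && is.infinite(odds2)) NaN else
      odds1 / odds2
    return(structure(out, degenerate = TRUE))
  }
  (p1 / (1 - p1)) / (p2 / (1 - p2))
}

#' Woolf confidence interval for the odds ratio of a 2x2 table
#'
#' `OR = (a/b) / (c/d)`, `SE(ln OR) = sqrt(1/a + 1/b + 1/c + 1/d)`, bounds
#' `exp(ln OR -+ z * SE)`. With any zero cell the default is an error; with
#' `zero_correction = TRUE` the Haldane-Anscombe +0.5 is added to every
#' cell and the result carries `corrected = TRUE`.
#'
#' @param t A [contingency_2x2()] (or a list with fields a, b, c, d).
#' @param level Confidence level (default 0.95).
#' @param zero_correction Apply +0.5 to all cells when any cell is zero.
#' @return List with `or`, `se_log`, `ci_low`, `ci_high`, `corrected`.
#' @examples
#' ci_from_counts(list(a = 382, b = 365, c = 442, d = 1211))
#' @export
ci_from_counts <- function(t, level = 0.95, zero_correction = FALSE) {
  a <- t$a; b <- t$b; cc <- t$c; d <- t$d
  stopifnot(all(c(a, b, cc, d) >= 0), level > 0, level < 1)
  corrected <- FALSE
  if (any(c(a, b, cc, d) == 0)) {
    if (!zero_correction) {
      stop("zero cell in 2x2 table; set zero_correction = TRUE for the ",
           "Haldane-Anscombe +0.5 adjustment", call. = FALSE)
    }
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
    corrected <- TRUE
  }
  or <- (a / b) / (cc / d)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or = or, se_log = se,
       ci_low = exp(log(or) - z * se), ci_high = exp(log(or) + z * se),
       corrected = corrected)
}

#' Relationship report over a learned structure
#'
#' One row per DAG arc whose child is a pain variable. Binary evidence
#' contributes one row (evidence level "yes"; for gender, "female");
#' the three-level age group expands into one row per level, dichotomized
#' level-vs-rest. Conditional percentages are empirical frequencies from
#' the 2x2 counts (`100 * a/(a+b)` and `100 * c/(c+d)`); OR and CI come
#' from the same counts. Row order is fixed: demographic evidence first
#' (age before gender, levels in schema order), then pain-to-pain arcs in
#' topological order of the DAG with lexicographic ties.
#'
#' @param data A [categorical_dataset()].
#' @param g A learned (or reference) `bn_dag` over the data's variables.
#' @param level Confidence level for the CIs.
#' @param zero_correction Passed to [ci_from_counts()].
#' @param extra_pairs Optional data frame with columns `parent`,
#'   `parent_level`, `child` appended after the arc-derived rows.
#' @return Data frame with columns `relationship`, `evidence`,
#'   `evidence_level`, `event`, `yes_pct`, `no_pct`, `odds_ratio`,
#'   `ci_lower`, `ci_upper`, `a`, `b`, `c`, `d`, `corrected`.
#' @export
relationship_table <- function(data, g, level = 0.95,
                               zero_correction = FALSE,
                               extra_pairs = NULL) {
  schema <- dataset_schema(data)
  check_dag_over(g, schema)
  roles <- vapply(schema, `[[`, "", "role")
  pain <- schema_names(schema)[roles == "pain"]
  demo <- schema_names(schema)[roles == "demographic"]

  pairs <- list()
  push <- function(parent, plevel, child) {
    pairs[[length(pairs) + 1L]] <<- list(parent = parent, plevel = plevel,
                                         child = child)
  }
  arcs <- g$arcs[g$arcs[, 2L] %in% pain, , drop = FALSE]
  # demographic evidence first: age then gender by schema order
  for (d in intersect(c("age", "gender"), demo)) {
    kids <- sort(arcs[arcs[, 1L] == d, 2L])
    for (ch in kids) {
      if (n_levels(schema, d) > 2L) {
        for (lv in schema[[d]]$levels) push(d, lv, ch)
      } else {
        push(d, schema[[d]]$levels[1L], ch)
      }
    }
  }
  # pain-to-pain in topological parent order
  topo <- topological_order(g)
  for (p in topo[topo %in% pain]) {
    kids <- sort(arcs[arcs[, 1L] == p & !(arcs[, 1L] %in% demo), 2L])
    for (ch in kids) push(p, "yes", ch)
  }
  if (!is.null(extra_pairs)) {
    for (k in seq_len(nrow(extra_pairs))) {
      push(extra_pairs$parent[k], extra_pairs$parent_level[k],
           extra_pairs$child[k])
    }
  }

  rows <- lapply(pairs, function(pr) {
    ev <- stats::setNames(pr$plevel, pr$parent)
    et <- stats::setNames("yes", pr$child)
    t2 <- contingency_2x2(data, ev, et)
    ci <- ci_from_counts(t2, level = level,
                         zero_correction = zero_correction)
    lab <- if (roles[[pr$parent]] == "demographic") {
      paste0(pr$parent, ":", pr$plevel, " -> ", pr$child)
    } else paste0(pr$parent, " -> ", pr$child)
    data.frame(
      relationship = lab, evidence = pr$parent,
      evidence_level = pr$plevel, event = pr$child,
      yes_pct = 100 * t2$a / (t2$a + t2$b),
      no_pct = 100 * t2$c / (t2$c + t2$d),
      odds_ratio = ci$or, ci_lower = ci$ci_low, ci_upper = ci$ci_high,
      a = t2$a, b = t2$b, c = t2$c, d = t2$d, corrected = ci$corrected,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Model-based relationship percentages
#'
#' The Eq.-style alternative to the empirical report: conditional
#' probabilities obtained by exact queries on a fitted network instead of
#' 2x2 counts, labeled accordingly. Useful for comparing the empirical and
#' model-marginalized readings of the same relationships.
#'
#' @param net A `bayes_net`.
#' @param pairs Data frame with columns `parent`, `parent_level`, `child`
#'   (default: the bundled association pairs).
#' @return Data frame with `relationship`, `yes_pct`, `no_pct`,
#'   `odds_ratio` (from the two probabilities), and `basis = "model"`.
#' @export
model_relationship_table <- function(net, pairs = NULL) {
  stopifnot(inherits(net, "bayes_net"))
  if (is.null(pairs)) {
    pairs <- reference_associations()[c("parent", "parent_level", "child")]
  }
  schema <- net$schema
  rows <- lapply(seq_len(nrow(pairs)), function(k) {
    p <- pairs$parent[k]; lv <- pairs$parent_level[k]; ch <- pairs$child[k]
    tgt <- stats::setNames("yes", ch)
    p1 <- query_conditional(net, tgt, stats::setNames(lv, p))
    other <- setdiff(schema[[p]]$levels, lv)
    if (length(other) == 1L) {
      p2 <- query_conditional(net, tgt, stats::setNames(other, p))
    } else {
      # level-vs-rest for multi-level evidence: mix the complement levels
      # by their conditional weights
      marg <- vapply(schema[[p]]$levels, function(l) {
        query_conditional(net, stats::setNames(l, p))
      }, 0)
      w <- marg[other] / sum(marg[other])
      p2 <- sum(w * vapply(other, function(l) {
        query_conditional(net, tgt, stats::setNames(l, p))
      }, 0))
    }
    data.frame(
      relationship = if (schema[[p]]$role == "demographic") {
        paste0(p, ":", lv, " -> ", ch)
      } else paste0(p, " -> ", ch),
      yes_pct = 100 * p1, no_pct = 100 * p2,
      odds_ratio = odds_ratio_from_probs(p1, p2), basis = "model",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
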