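# File formats and the end-to-end pipeline: CSV cohorts, DOT graphs, JSON
# networks and traces, TSV reports, and a five-stage driver.

#' Read a cohort CSV as a categorical dataset
#'
#' Expects a header of variable names and cells holding level labels
#' (comma-separated, UTF-8, case-sensitive labels, no index column).
#' Unknown labels and missing cells are schema errors naming the offending
#' row: the pipeline assumes complete-case data.
#'
#' @param path CSV file path.
#' @param schema Schema to validate against (default [pain_schema()]).
#' @return A [categorical_dataset()].
#' @export
read_dataset_csv <- function(path, schema = pain_schema()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  categorical_dataset(df, schema)
}

#' Write a categorical dataset as CSV
#' @param data A [categorical_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset_csv <- function(data, path) {
  df <- as.data.frame(lapply(data, as.character),
                      stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a DAG as annotated DOT text
#'
#' Arcs can carry odds-ratio annotations: an arc is drawn solid black and
#' labeled with its OR (3 decimals) when OR > 1 and the CI excludes 1;
#' otherwise it is drawn dotted blue (inverse or non-significant
#' association). Unannotated arcs are plain solid.
#'
#' @param g A `bn_dag`.
#' @param annotations Optional data frame with columns `from`, `to`, `or`,
#'   `ci_lower`, `ci_upper` (e.g. derived from [relationship_table()]).
#' @param name Graph name in the DOT header.
#' @return A single DOT string (also invisibly returned by `cat`-style
#'   writers); write it with `writeLines`.
#' @export
write_dag_dot <- function(g, annotations = NULL, name = "pain_network") {
  stopifnot(inherits(g, "bn_dag"))
  lines <- c(sprintf("digraph %s {", name),
             sprintf("  %s;", g$nodes))
  if (nrow(g$arcs)) {
    for (k in seq_len(nrow(g$arcs))) {
      from <- g$arcs[k, 1L]; to <- g$arcs[k, 2L]
      attr <- ""
      if (!is.null(annotations)) {
        hit <- annotations$from == from & annotations$to == to
        if (any(hit)) {
          row <- annotations[which(hit)[1L], ]
          sig <- row$or > 1 && (row$ci_lower > 1 || row$ci_upper < 1)
          style <- if (sig) "style=solid, color=black" else
            "style=dotted, color=blue"
          attr <- sprintf(" [label=\"%.3f\", %s]", row$or, style)
        }
      }
      lines <- c(lines, sprintf("  %s -> %s%s;", from, to, attr))
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Marginal prevalence table of a cohort
#'
#' Counts and percentage prevalence per pain variable, matching the layout
#' of the published summary (`prevalence` rounded to 1 decimal place).
#'
#' @param data A [categorical_dataset()].
#' @return Data frame with `variable`, `yes`, `no`, `prevalence`.
#' @export
prevalence_table <- function(data) {
  schema <- dataset_schema(data)
  pain <- schema_names(schema)[vapply(schema, `[[`, "", "role") == "pain"]
  rows <- lapply(pain, function(v) {
    yes <- sum(data[[v]] == "yes")
    no <- nrow(data) - yes
    data.frame(variable = v, yes = yes, no = no,
               prevalence = round(100 * yes / (yes + no), 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# --- JSON serialization -----------------------------------------------------

#' Serialize a fitted network to JSON
#'
#' Node -> (levels, parents, row-major probability array in package
#' configuration order, unobserved flags) plus the arc list.
#'
#' @param net A `bayes_net`.
#' @param path Optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to `path`).
#' @export
write_network_json <- function(net, path = NULL) {
  stopifnot(inherits(net, "bayes_net"))
  obj <- list(
    nodes = lapply(net$cpts, function(ct) {
      list(parents = ct$parents,
           prob = as.vector(t(ct$prob)),
           unobserved = ct$unobserved)
    }),
    levels = lapply(net$schema, `[[`, "levels"),
    roles = lapply(net$schema, `[[`, "role"),
    arcs = apply(net$dag$arcs, 1L, function(r) list(from = r[[1L]],
                                                    to = r[[2L]]))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read a fitted network back from JSON
#' @param path File written by [write_network_json()].
#' @return A `bayes_net`.
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  nm <- names(obj$nodes)
  schema <- lapply(nm, function(v) {
    variable_spec(v, unlist(obj$levels[[v]]), obj$roles[[v]])
  })
  names(schema) <- nm
  arcs <- if (length(obj$arcs)) {
    do.call(rbind, lapply(obj$arcs, function(a) c(a$from, a$to)))
  } else NULL
  g <- dag(nm, arcs)
  cpts <- lapply(nm, function(v) {
    nd <- obj$nodes[[v]]
    pars <- as.character(unlist(nd$parents))
    sizes <- vapply(pars, function(p) length(schema[[p]]$levels), 1L)
    r <- length(schema[[v]]$levels)
    ncfg <- prod(c(1L, sizes))
    prob <- matrix(unlist(nd$prob), nrow = ncfg, ncol = r, byrow = TRUE)
    list(parents = pars, prob = prob,
         unobserved = as.logical(unlist(nd$unobserved)))
  })
  names(cpts) <- nm
  new_bayes_net(g, schema_check(schema), cpts)
}

# --- pipeline ---------------------------------------------------------------

#' Run the full analysis pipeline
#'
#' Five stages: (1) simulate a cohort from the default truth network, or
#' load one from CSV; (2) build the demographic blacklist; (3) learn the
#' structure by constrained hill climbing; (4) fit CPTs by maximum
#' likelihood; (5) compute the relationship report. Artifacts written to
#' `out_dir`: `cohort.csv`, `network.dot`, `network.json`, `cpts.json`
#' (alias of the fitted network), `relationships.tsv`, `prevalence.tsv`,
#' `search_trace.json`, `forest_plot.csv` (log-scale OR plot data) and
#' `run_log.txt`. Given a fixed seed every data artifact is byte-identical
#' across runs (the log additionally records elapsed times).
#'
#' @param out_dir Output directory (created if needed).
#' @param input_csv Optional cohort CSV; when `NULL` a cohort is simulated.
#' @param n,seed Simulation size and seed (ignored when `input_csv` given;
#'   the seed also feeds optional search restarts).
#' @param constraints Arc constraints (default demographic blacklist).
#' @param pseudocount CPT smoothing (default 0 = pure MLE).
#' @param level Confidence level for CIs.
#' @param restarts Hill-climbing restarts.
#' @param zero_correction Passed to the relationship report.
#' @return Invisible list with `data`, `trace`, `net`, `report`,
#'   `prevalence`, and the output paths.
#' @export
run_pipeline <- function(out_dir, input_csv = NULL, n = 2400L, seed = 1L,
                         constraints = demographic_blacklist(),
                         pseudocount = 0, level = 0.95, restarts = 0L,
                         zero_correction = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    log_lines <<- c(log_lines, sprintf(
      "stage=%s seed=%d elapsed=%.2fs", name, seed,
      proc.time()[["elapsed"]] - t0))
    res
  }
  data <- stage("data", {
    if (is.null(input_csv)) {
      forward_sample(generator_config(n = n, seed = seed))
    } else {
      read_dataset_csv(input_csv)
    }
  })
  constraints <- stage("constraints", constraints)
  trace <- stage("structure", hill_climb(data, constraints,
                                         restarts = restarts, seed = seed))
  net <- stage("parameters", suppressWarnings(
    fit_mle_cpts(data, trace$dag, pseudocount = pseudocount)))
  report <- stage("report", relationship_table(
    data, trace$dag, level = level, zero_correction = zero_correction))

  prev <- prevalence_table(data)
  ann <- data.frame(from = report$evidence, to = report$event,
                    or = report$odds_ratio, ci_lower = report$ci_lower,
                    ci_upper = report$ci_upper, stringsAsFactors = FALSE)
  paths <- list(
    cohort = file.path(out_dir, "cohort.csv"),
    dot = file.path(out_dir, "network.dot"),
    network = file.path(out_dir, "network.json"),
    report = file.path(out_dir, "relationships.tsv"),
    prevalence = file.path(out_dir, "prevalence.tsv"),
    trace = file.path(out_dir, "search_trace.json"),
    forest = file.path(out_dir, "forest_plot.csv"),
    log = file.path(out_dir, "run_log.txt"))
  write_dataset_csv(data, paths$cohort)
  writeLines(write_dag_dot(trace$dag, ann), paths$dot)
  write_network_json(net, paths$network)
  rep_out <- report
  for (cn in c("yes_pct", "no_pct", "odds_ratio", "ci_lower", "ci_upper")) {
    rep_out[[cn]] <- round(rep_out[[cn]], 3L)
  }
  utils::write.table(rep_out, paths$report, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(prev, paths$prevalence, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeLines(jsonlite::toJSON(list(moves = trace$trace,
                                   final_score = trace$score),
                              dataframe = "rows", auto_unbox = TRUE,
                              digits = NA, pretty = TRUE), paths$trace)
  forest <- data.frame(relationship = report$relationship,
                       log_or = log(report$odds_ratio),
                       log_ci_lower = log(report$ci_lower),
                       log_ci_upper = log(report$ci_upper),
                       stringsAsFactors = FALSE)
  utils::write.csv(forest, paths$forest, row.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("painbn %s | R %s", "0.1.0",
                       paste(R.version$major, R.version$minor, sep = ".")),
               log_lines), paths$log)
  invisible(list(data = data, trace = trace, net = net, report = report,
                 prevalence = prev, paths = paths))
}
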