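#' Declare a categorical survey variable
#'
#' A variable specification pairs a name with an ordered set of level labels
#' and a role. Demographic variables (gender, age group) are exogenous in the
#' network analysis; pain variables are binary indicators with levels
#' `c("no", "yes")` so that level index 2 always means "pain present".
#'
#' @param name Variable name (non-empty string, unique within a schema).
#' @param levels Character vector of at least two unique, non-empty level
#'   labels. Order is significant: it fixes CPT row layout and report columns.
#' @param role Either `"demographic"` or `"pain"`. Pain variables must have
#'   exactly two levels.
#' @return An object of class `variable_spec`.
#' @examples
#' variable_spec("neck", c("no", "yes"), "pain")
#' @export
variable_spec <- function(name, levels, role = c("pain", "demographic")) {
  role <- match.arg(role)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("variable name must be a single non-empty string", call. = FALSE)
  }
  if (!is.character(levels) || length(levels) < 2L) {
    stop("'", name, "': at least two levels are required", call. = FALSE)
  }
  if (anyDuplicated(levels) || any(!nzchar(levels))) {
    stop("'", name, "': levels must be unique and non-empty", call. = FALSE)
  }
  if (role == "pain" && length(levels) != 2L) {
    stop("'", name, "': pain variables are binary (two levels)", call. = FALSE)
  }
  structure(list(name = name, levels = levels, role = role),
            class = "variable_spec")
}

#' @export
print.variable_spec <- function(x, ...) {
  cat(sprintf("<variable_spec> %s (%s): %s\n",
              x$name, x$role, paste(x$levels, collapse = " < ")))
  invisible(x)
}

#' The default chronic-pain survey schema
#'
#' Twelve variables: gender (female/male), age group (young/middle/senior)
#' and ten binary pain-location indicators. "None of the above" responses are
#' represented implicitly as all pain indicators equal to "no"; as a
#' deterministic function of the other columns it is degenerate as a network
#' node and is not part of the schema.
#'
#' @return A named list of [variable_spec()] objects, in schema order
#'   (demographics first, then pain sites).
#' @export
pain_schema <- function() {
  pain <- c("headache", "all_body", "face", "neck", "back",
            "stomach", "hip", "knee", "hand", "foot")
  specs <- c(
    list(variable_spec("gender", c("female", "male"), "demographic"),
         variable_spec("age", c("young", "middle", "senior"), "demographic")),
    lapply(pain, function(v) variable_spec(v, c("no", "yes"), "pain"))
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

schema_names <- function(schema) vapply(schema, `[[`, "", "name")

schema_check <- function(schema) {
  if (!is.list(schema) || length(schema) == 0L) {
    stop("schema must be a non-empty list of variable_spec objects",
         call. = FALSE)
  }
  ok <- vapply(schema, inherits, TRUE, "variable_spec")
  if (!all(ok)) stop("schema entries must be variable_spec objects",
                     call. = FALSE)
  nm <- schema_names(schema)
  if (anyDuplicated(nm)) stop("duplicate variable names in schema",
                              call. = FALSE)
  if (!identical(names(schema), nm)) names(schema) <- nm
  schema
}

#' Build a categorical dataset from a data frame
#'
#' Wraps a rectangular table of level labels (or factors) as a validated
#' `categorical_dataset`: a data frame of factors whose levels match the
#' schema exactly, with the schema attached. All learning and reporting
#' functions in the package consume this class.
#'
#' @param df Data frame with one column per schema variable (extra columns
#'   are an error); cells hold level labels.
#' @param schema Named list of [variable_spec()]; default [pain_schema()].
#' @return A `categorical_dataset` (a data frame of factors with attributes
#'   `schema`).
#' @export
categorical_dataset <- function(df, schema = pain_schema()) {
  schema <- schema_check(schema)
  nm <- schema_names(schema)
  if (!is.data.frame(df)) stop("df must be a data frame", call. = FALSE)
  missing_cols <- setdiff(nm, names(df))
  if (length(missing_cols)) {
    stop("missing variables: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(df), nm)
  if (length(extra)) {
    stop("unknown variables: ", paste(extra, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) < 1L) stop("dataset must contain at least one record",
                          call. = FALSE)
  out <- df[nm]
  for (v in nm) {
    col <- as.character(out[[v]])
    bad <- which(is.na(col) | !(col %in% schema[[v]]$levels))
    if (length(bad)) {
      stop(sprintf("variable '%s': invalid level '%s' at row %d",
                   v, col[bad[1L]], bad[1L]), call. = FALSE)
    }
    out[[v]] <- factor(col, levels = schema[[v]]$levels)
  }
  rownames(out) <- NULL
  structure(out, schema = schema,
            class = c("categorical_dataset", "data.frame"))
}

dataset_schema <- function(data) {
  sc <- attr(data, "schema")
  if (is.null(sc)) stop("not a categorical_dataset: schema attribute missing",
                        call. = FALSE)
  sc
}

#' @export
print.categorical_dataset <- function(x, ...) {
  sc <- dataset_schema(x)
  cat(sprintf("<categorical_dataset> %d records x %d variables\n",
              nrow(x), length(sc)))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat(sprintf("... %d more records\n", nrow(x) - 6L))
  invisible(x)
}

# 1-based level index matrix; columns in schema order.
dataset_indices <- function(data) {
  sc <- dataset_schema(data)
  m <- vapply(schema_names(sc), function(v) as.integer(data[[v]]),
              integer(nrow(data)))
  if (!is.matrix(m)) m <- matrix(m, nrow = nrow(data))
  colnames(m) <- schema_names(sc)
  m
}

n_levels <- function(schema, v) length(schema[[v]]$levels)
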