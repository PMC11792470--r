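#' Declare which columns play which causal role
#'
#' A role map partitions the columns of a sample-by-variable table into the
#' four nodes of the mediation graph: treatment `T`, mediators `M`, outcomes
#' `Y`, and pretreatment covariates `X`.  Mediators and outcomes may be given
#' as literal column names or as [starts_with()] prefix selectors, which is
#' convenient when hundreds of taxa or metabolites share a naming prefix.
#'
#' @param treatment character vector of treatment column names (non-empty).
#' @param mediators character names and/or [starts_with()] selectors.
#' @param outcomes character names and/or [starts_with()] selectors.
#' @param pretreatment character names and/or selectors; may be empty.
#' @return an object of class `role_map`.
#' @examples
#' role_map("treat", mediators = starts_with("diet"), outcomes = c("gA", "gB"))
#' @export
role_map <- function(treatment, mediators, outcomes, pretreatment = character()) {
  if (length(treatment) == 0) {
    abort("`treatment` must name at least one column", "medipath_config_error")
  }
  structure(
    list(
      treatment = treatment,
      mediators = as_selection(mediators),
      outcomes = as_selection(outcomes),
      pretreatment = as_selection(pretreatment)
    ),
    class = "role_map"
  )
}

#' Prefix selector for role maps
#'
#' Matches every column whose name starts with `prefix`, in table order.
#'
#' @param prefix string prefix.
#' @return a selector usable inside [role_map()].
#' @export
starts_with <- function(prefix) {
  stopifnot(is.character(prefix), length(prefix) == 1, nzchar(prefix))
  structure(list(prefix = prefix), class = "medipath_selector")
}

as_selection <- function(x) {
  if (inherits(x, "medipath_selector")) return(list(x))
  if (is.character(x)) return(as.list(x))
  if (is.list(x)) {
    ok <- vapply(x, function(e) is.character(e) || inherits(e, "medipath_selector"),
                 logical(1))
    if (all(ok)) return(x)
  }
  abort("role selections must be column names or starts_with() selectors",
        "medipath_config_error")
}

#' Expand a selection pattern against available column names
#'
#' Literal names must match exactly; [starts_with()] selectors match by
#' prefix and return columns in table order.  Expansion is deterministic for
#' a fixed table.
#'
#' @param pattern a column name, a [starts_with()] selector, or a list mixing
#'   the two.
#' @param columns character vector of available column names.
#' @return matching column names, in table order for prefix selectors.
#' @examples
#' expand_selection(starts_with("diet"), c("diet_a", "diet_b", "sleep"))
#' @export
expand_selection <- function(pattern, columns) {
  specs <- as_selection(pattern)
  out <- character()
  for (s in specs) {
    if (inherits(s, "medipath_selector")) {
      hits <- columns[base::startsWith(columns, s$prefix)]
      if (length(hits) == 0) {
        abort(sprintf("prefix '%s' matched no columns", s$prefix),
              "medipath_empty_selection")
      }
    } else {
      if (!s %in% columns) {
        abort(sprintf("column '%s' not found", s), "medipath_empty_selection")
      }
      hits <- s
    }
    out <- c(out, setdiff(hits, out))
  }
  out
}

#' Assemble a role-partitioned mediation dataset
#'
#' Splits one sample-by-variable table into aligned treatment, mediator,
#' outcome, and pretreatment blocks.  Every row is one analysis unit; blocks
#' stay aligned by row order.  Columns assigned to no role are dropped with a
#' warning (real tables carry metadata columns).  Missing values in any role
#' block are rejected: incomplete samples must be handled upstream.
#'
#' Categorical treatment (and pretreatment) columns are stored as factors.
#' The treatment reference level defaults to the lexicographically first
#' observed level and can be overridden with `treatment_ref`; all downstream
#' contrasts name levels explicitly.
#'
#' @param table data.frame with unique sample identifiers as row names (or
#'   `NULL` row names, in which case row numbers are used).
#' @param roles a [role_map()].
#' @param treatment_ref optional named character vector giving the reference
#'   level per categorical treatment column.
#' @return an object of class `mediation_data` with elements `sample_ids`,
#'   `treatments` (data.frame), `mediators` (numeric matrix, n x K),
#'   `outcomes` (numeric matrix, n x J) and `pretreatment` (data.frame,
#'   possibly zero columns).
#' @examples
#' df <- data.frame(treat = c("a", "b", "a", "b"),
#'                  diet_fruit = rnorm(4), diet_cereal = rnorm(4),
#'                  genusA = rnorm(4), genusB = rnorm(4))
#' md <- mediation_data(df, role_map("treat", starts_with("diet"),
#'                                   c("genusA", "genusB")))
#' @export
mediation_data <- function(table, roles, treatment_ref = NULL) {
  stopifnot(inherits(roles, "role_map"))
  table <- as.data.frame(table)
  if (nrow(table) < 2) {
    abort("need at least 2 samples", "medipath_config_error")
  }
  cols <- colnames(table)
  t_cols <- roles$treatment
  missing_t <- setdiff(t_cols, cols)
  if (length(missing_t)) {
    abort(sprintf("treatment column(s) not found: %s",
                  paste(missing_t, collapse = ", ")), "medipath_config_error")
  }
  m_cols <- expand_selection(roles$mediators, cols)
  y_cols <- expand_selection(roles$outcomes, cols)
  x_cols <- if (length(roles$pretreatment)) {
    expand_selection(roles$pretreatment, cols)
  } else {
    character()
  }

  blocks <- list(treatment = t_cols, mediators = m_cols,
                 outcomes = y_cols, pretreatment = x_cols)
  for (i in seq_along(blocks)) {
    for (j in seq_along(blocks)) {
      if (i < j) {
        shared <- intersect(blocks[[i]], blocks[[j]])
        if (length(shared)) {
          abort(sprintf("column '%s' assigned to both %s and %s",
                        shared[1], names(blocks)[i], names(blocks)[j]),
                "medipath_role_conflict")
        }
      }
    }
  }
  if (length(m_cols) == 0 || length(y_cols) == 0) {
    abort("mediator and outcome sets must be non-empty", "medipath_config_error")
  }
  unused <- setdiff(cols, unlist(blocks))
  if (length(unused)) {
    warning(sprintf("dropping %d unassigned column(s): %s",
                    length(unused), paste(utils::head(unused, 5), collapse = ", ")),
            call. = FALSE)
  }

  for (cc in c(m_cols, y_cols)) {
    if (!is.numeric(table[[cc]])) {
      abort(sprintf("mediator/outcome column '%s' is not numeric", cc),
            "medipath_type_error")
    }
  }

  ids <- rownames(table)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(table)))
  if (anyDuplicated(ids)) {
    abort("duplicate sample identifiers", "medipath_format_error")
  }

  treatments <- table[, t_cols, drop = FALSE]
  for (cc in t_cols) {
    v <- treatments[[cc]]
    if (!is.numeric(v)) {
      lev <- sort(unique(as.character(v)))
      if (length(lev) < 2) {
        abort(sprintf("categorical treatment '%s' has fewer than 2 levels", cc),
              "medipath_config_error")
      }
      ref <- treatment_ref[[cc]] %||% lev[1]
      if (!ref %in% lev) {
        abort(sprintf("reference level '%s' not observed in '%s'", ref, cc),
              "medipath_level_error")
      }
      treatments[[cc]] <- factor(as.character(v), levels = c(ref, setdiff(lev, ref)))
    }
  }

  mediators <- as.matrix(table[, m_cols, drop = FALSE])
  outcomes <- as.matrix(table[, y_cols, drop = FALSE])
  pretreatment <- table[, x_cols, drop = FALSE]
  for (cc in x_cols) {
    if (!is.numeric(pretreatment[[cc]])) {
      pretreatment[[cc]] <- factor(as.character(pretreatment[[cc]]))
    }
  }

  if (anyNA(treatments) || anyNA(mediators) || anyNA(outcomes) || anyNA(pretreatment)) {
    abort("missing values in a role block; drop incomplete samples upstream",
          "medipath_missing_error")
  }

  structure(
    list(sample_ids = ids, treatments = treatments, mediators = mediators,
         outcomes = outcomes, pretreatment = pretreatment),
    class = "mediation_data"
  )
}

#' @export
print.mediation_data <- function(x, ...) {
  cat(sprintf(
    "mediation_data: %d samples | %d treatment var(s) | %d mediators | %d outcomes | %d covariates\n",
    length(x$sample_ids), ncol(x$treatments), ncol(x$mediators),
    ncol(x$outcomes), ncol(x$pretreatment)))
  invisible(x)
}

#' @export
dim.mediation_data <- function(x) {
  c(length(x$sample_ids),
    ncol(x$treatments) + ncol(x$mediators) + ncol(x$outcomes) + ncol(x$pretreatment))
}

#' Number of samples in a mediation dataset
#' @param data a [mediation_data()] object.
#' @return integer sample count.
#' @export
n_samples <- function(data) length(data$sample_ids)

#' Read a sample-by-variable table
#'
#' CSV/TSV files must carry a header row and sample identifiers in the first
#' column; BIOM feature tables (JSON or HDF5 dialect, read through the
#' biomformat package) are transposed so that rows are samples.
#'
#' @param path file path.
#' @param format one of `"csv"`, `"tsv"`, `"biom"`; default guesses from the
#'   file extension.
#' @return data.frame with sample identifiers as row names.
#' @export
read_table <- function(path, format = c("auto", "csv", "tsv", "biom")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", biom = "biom",
                     abort(sprintf("cannot guess format from extension '%s'", ext),
                           "medipath_format_error"))
  }
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), "medipath_format_error")
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("the biomformat package is required to read BIOM files",
            "medipath_format_error")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix")  # features x samples
    tab <- as.data.frame(t(m))
    if (anyDuplicated(rownames(tab))) {
      abort("duplicate sample identifiers in BIOM file", "medipath_format_error")
    }
    return(tab)
  }
  sep <- if (format == "csv") "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2) {
    abort("expected an ID column plus at least one variable", "medipath_format_error")
  }
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) {
    abort("duplicate sample identifiers", "medipath_format_error")
  }
  tab <- tab[, -1, drop = FALSE]
  rownames(tab) <- ids
  tab
}

# reassemble role blocks into one table (round-trip check, CSV export)
#' Reassemble the role blocks of a mediation dataset into one table
#' @param data a [mediation_data()] object.
#' @return data.frame with treatment, mediator, outcome, then covariate columns.
#' @export
as_table <- function(data) {
  stopifnot(inherits(data, "mediation_data"))
  out <- cbind(data$treatments,
               as.data.frame(data$mediators),
               as.data.frame(data$outcomes))
  if (ncol(data$pretreatment)) out <- cbind(out, data$pretreatment)
  rownames(out) <- data$sample_ids
  out
}
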