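# -- design encoding ----------------------------------------------------------
# Treatment and categorical covariates are one-hot encoded against the stored
# reference level; numeric columns pass through.  The encoding is frozen at
# fit time so prediction on unseen levels is an error, not a silent NA.

make_design_spec <- function(df) {
  spec <- lapply(seq_along(df), function(i) {
    v <- df[[i]]
    if (is.factor(v)) {
      list(name = names(df)[i], type = "factor", levels = levels(v))
    } else {
      list(name = names(df)[i], type = "numeric")
    }
  })
  names(spec) <- names(df)
  spec
}

encode_design <- function(spec, df) {
  n <- nrow(df)
  cols <- list()
  for (s in spec) {
    v <- df[[s$name]]
    if (is.null(v)) {
      abort(sprintf("design column '%s' missing", s$name), "medipath_dim_error")
    }
    if (s$type == "factor") {
      v <- as.character(v)
      bad <- setdiff(unique(v), s$levels)
      if (length(bad)) {
        abort(sprintf("unseen level '%s' in '%s'", bad[1], s$name),
              "medipath_level_error")
      }
      for (lev in s$levels[-1]) {
        cols[[paste0(s$name, lev)]] <- as.numeric(v == lev)
      }
    } else {
      cols[[s$name]] <- as.numeric(v)
    }
  }
  if (length(cols) == 0) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  do.call(cbind, cols)
}

# -- mediation model ----------------------------------------------------------

#' Assemble an (unfitted) mediation model
#'
#' Combines a mediator family (regressing mediators on treatment and
#' pretreatment covariates) and an outcome family (regressing outcomes on
#' treatment, mediators, and covariates) into the mediation causal graph.
#' Edges `T->M`, `T->Y`, and `M->Y` are all present by default and can be
#' removed with [nullify()]; the covariate edges `X -> {M, Y}` always remain.
#'
#' @param data a [mediation_data()] object supplying roles and encodings.
#' @param outcome_family a [model_family()] for `T, M, X -> Y`.
#' @param mediator_family a [model_family()] for `T, X -> M`.
#' @return an object of class `mediation_model` (unfitted).
#' @export
multimedia <- function(data, outcome_family = family_linear(),
                       mediator_family = family_linear()) {
  stopifnot(inherits(data, "mediation_data"))
  check_family_contract(mediator_family)
  check_family_contract(outcome_family)
  structure(
    list(
      mediator_family = mediator_family,
      outcome_family = outcome_family,
      edge_mask = c("T->M" = TRUE, "T->Y" = TRUE, "M->Y" = TRUE),
      treatment_spec = make_design_spec(data$treatments),
      pretreatment_spec = make_design_spec(data$pretreatment),
      mediator_names = colnames(data$mediators),
      outcome_names = colnames(data$outcomes),
      mediator_fit = NULL,
      outcome_fit = NULL
    ),
    class = "mediation_model"
  )
}

#' @export
print.mediation_model <- function(x, ...) {
  edges <- paste(names(x$edge_mask)[x$edge_mask], collapse = ", ")
  cat(sprintf("mediation_model [%s]: mediator=%s, outcome=%s (%s)\n",
              if (is_fitted(x)) "fitted" else "unfitted",
              x$mediator_family$name, x$outcome_family$name,
              if (nzchar(edges)) paste("edges:", edges) else "no causal edges"))
  invisible(x)
}

is_fitted <- function(model) {
  !is.null(model$mediator_fit) && !is.null(model$outcome_fit)
}

check_fitted <- function(model) {
  if (!is_fitted(model)) {
    abort("model must be estimated first (see estimate())", "medipath_state_error")
  }
  invisible(model)
}

mediator_design <- function(model, treatments, pretreatment) {
  parts <- list()
  if (model$edge_mask[["T->M"]]) {
    parts$t <- encode_design(model$treatment_spec, treatments)
  }
  parts$x <- encode_design(model$pretreatment_spec, pretreatment)
  bind_design(parts, nrow(treatments))
}

outcome_design <- function(model, treatments, mediators, pretreatment) {
  parts <- list()
  if (model$edge_mask[["T->Y"]]) {
    parts$t <- encode_design(model$treatment_spec, treatments)
  }
  if (model$edge_mask[["M->Y"]]) {
    m <- as.matrix(mediators)
    colnames(m) <- model$mediator_names
    parts$m <- m
  }
  parts$x <- encode_design(model$pretreatment_spec, pretreatment)
  bind_design(parts, nrow(treatments))
}

bind_design <- function(parts, n) {
  parts <- Filter(function(p) ncol(p) > 0, parts)
  if (length(parts) == 0) {
    return(matrix(numeric(0), nrow = n, ncol = 0))
  }
  do.call(cbind, parts)
}

#' Estimate both submodels of a mediation model
#'
#' Fits the mediator family on `(T, X) -> M` and the outcome family on
#' `(T, M, X) -> Y`, honoring the edge mask (a removed edge excludes the
#' corresponding columns from the design).  Returns a new fitted model; the
#' input is untouched.
#'
#' @param model a `mediation_model`.
#' @param data a [mediation_data()] with the roles the model was defined on.
#' @return the fitted `mediation_model`.
#' @export
estimate <- function(model, data) {
  stopifnot(inherits(model, "mediation_model"), inherits(data, "mediation_data"))
  md <- mediator_design(model, data$treatments, data$pretreatment)
  model$mediator_fit <- tryCatch(
    fit_family(model$mediator_family, md, data$mediators),
    error = function(e) {
      abort(paste0("mediator model fit failed: ", conditionMessage(e)),
            "medipath_fit_error")
    }
  )
  od <- outcome_design(model, data$treatments, data$mediators, data$pretreatment)
  model$outcome_fit <- tryCatch(
    fit_family(model$outcome_family, od, data$outcomes),
    error = function(e) {
      abort(paste0("outcome model fit failed: ", conditionMessage(e)),
            "medipath_fit_error")
    }
  )
  model
}

# -- treatment profiles -------------------------------------------------------

#' Build a counterfactual treatment profile (t, t')
#'
#' A profile is a pair of per-sample treatment tables: `t_mediator` drives
#' the mediator counterfactuals `M(t)` and `t_outcome` drives the outcome's
#' direct path.  The standard contrast sets every row of a table to a single
#' level, so e.g. `t_mediator = control, t_outcome = treated` is the mixed
#' profile behind `Y(1, M(0))`.  Multilevel treatments and multiple
#' concurrent treatment columns are supported; every level must have been
#' seen at fit time.
#'
#' @param model a `mediation_model`.
#' @param data the [mediation_data()] supplying row count and defaults.
#' @param mediator_level,outcome_level single treatment value (or named
#'   vector, one entry per treatment column) applied to all samples; `NULL`
#'   keeps the observed assignments.
#' @param t_mediator,t_outcome alternatively, explicit per-sample tables.
#' @return an object of class `treatment_profile`.
#' @export
treatment_profile <- function(model, data, mediator_level = NULL,
                              outcome_level = NULL, t_mediator = NULL,
                              t_outcome = NULL) {
  obs <- data$treatments
  build <- function(level, explicit) {
    if (!is.null(explicit)) {
      explicit <- as.data.frame(explicit)
      if (nrow(explicit) != nrow(obs) || !identical(names(explicit), names(obs))) {
        abort("explicit profile table must match the treatment table shape",
              "medipath_dim_error")
      }
      out <- explicit
    } else if (!is.null(level)) {
      out <- obs
      if (is.null(names(level))) {
        if (ncol(obs) != 1) {
          abort("a named level per treatment column is required", "medipath_level_error")
        }
        names(level) <- names(obs)
      }
      for (cc in names(level)) {
        if (is.factor(out[[cc]])) out[[cc]] <- as.character(out[[cc]])
        out[[cc]][] <- level[[cc]]
      }
    } else {
      out <- obs
    }
    for (cc in names(out)) {
      sp <- model$treatment_spec[[cc]]
      if (sp$type == "factor") {
        vals <- as.character(out[[cc]])
        bad <- setdiff(unique(vals), sp$levels)
        if (length(bad)) {
          abort(sprintf("unseen treatment level '%s' in '%s'", bad[1], cc),
                "medipath_level_error")
        }
        out[[cc]] <- factor(vals, levels = sp$levels)
      }
    }
    out
  }
  structure(
    list(t_mediator = build(mediator_level, t_mediator),
         t_outcome = build(outcome_level, t_outcome)),
    class = "treatment_profile"
  )
}

#' @export
print.treatment_profile <- function(x, ...) {
  cat(sprintf("treatment_profile over %d samples (%s)\n",
              nrow(x$t_mediator), paste(names(x$t_mediator), collapse = ", ")))
  invisible(x)
}

# -- counterfactual prediction and sampling -----------------------------------

#' Predict mediators and outcomes under a treatment profile
#'
#' Computes `M_hat = E[M | t_mediator, X]` from the mediator model, then
#' `Y_hat = E[Y | t_outcome, M_hat, X]` from the outcome model — the
#' mediators fed to the outcome model are the counterfactual predictions,
#' not the observed mediators.  This is the plug-in propagation behind all
#' effect estimators.
#'
#' @param model a fitted `mediation_model`.
#' @param data a [mediation_data()] supplying covariates.
#' @param prof a [treatment_profile()]; default is the observed assignment.
#' @return list with matrices `mediators` (n x K) and `outcomes` (n x J).
#' @export
predict_counterfactual <- function(model, data, prof = NULL) {
  check_fitted(model)
  if (is.null(prof)) prof <- treatment_profile(model, data)
  if (nrow(prof$t_mediator) != n_samples(data)) {
    abort("profile and data disagree on sample count", "medipath_dim_error")
  }
  md <- mediator_design(model, prof$t_mediator, data$pretreatment)
  M <- predict(model$mediator_fit, md)
  od <- outcome_design(model, prof$t_outcome, M, data$pretreatment)
  Y <- predict(model$outcome_fit, od)
  list(mediators = M, outcomes = Y)
}

#' Sample mediators and outcomes under a treatment profile
#'
#' Ancestral sampling down the mediation graph: mediators are drawn from the
#' mediator family's sampler, plugged into the outcome design, and outcomes
#' drawn from the outcome sampler.
#'
#' @inheritParams predict_counterfactual
#' @param seed integer seed (required).
#' @param ... passed to the outcome sampler (e.g. `depths` for count models).
#' @return list with matrices `mediators` and `outcomes`.
#' @export
sample_counterfactual <- function(model, data, prof = NULL, seed, ...) {
  check_fitted(model)
  if (is.null(prof)) prof <- treatment_profile(model, data)
  if (nrow(prof$t_mediator) != n_samples(data)) {
    abort("profile and data disagree on sample count", "medipath_dim_error")
  }
  with_seed(seed, {
    md <- mediator_design(model, prof$t_mediator, data$pretreatment)
    M <- model$mediator_fit$family$sample(model$mediator_fit$params, md)
    colnames(M) <- model$mediator_names
    od <- outcome_design(model, prof$t_outcome, M, data$pretreatment)
    Y <- model$outcome_fit$family$sample(model$outcome_fit$params, od, ...)
    colnames(Y) <- model$outcome_names
    list(mediators = M, outcomes = Y)
  })
}

# observed levels of a single-column categorical treatment, reference first
treatment_levels <- function(model) {
  sp <- model$treatment_spec[[1]]
  if (sp$type != "factor") {
    abort("default contrasts need a categorical treatment; name values explicitly",
          "medipath_level_error")
  }
  sp$levels
}
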