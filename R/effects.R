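# encoded treatment design for a single constant level, repeated n times
constant_treatment_matrix <- function(model, level, n) {
  spec <- model$treatment_spec
  if (is.null(names(level))) {
    if (length(spec) != 1) {
      abort("a named level per treatment column is required", "medipath_level_error")
    }
    names(level) <- names(spec)[1]
  }
  cols <- list()
  for (s in spec) {
    v <- level[[s$name]]
    if (is.null(v)) {
      abort(sprintf("no level supplied for treatment '%s'", s$name),
            "medipath_level_error")
    }
    if (s$type == "factor") {
      v <- as.character(v)
      if (!v %in% s$levels) {
        abort(sprintf("unseen treatment level '%s' in '%s'", v, s$name),
              "medipath_level_error")
      }
      for (lev in s$levels[-1]) {
        cols[[paste0(s$name, lev)]] <- rep(as.numeric(v == lev), n)
      }
    } else {
      cols[[s$name]] <- rep(as.numeric(v), n)
    }
  }
  if (length(cols) == 0) matrix(numeric(0), n, 0) else do.call(cbind, cols)
}

# predicted mediators under a constant treatment level (NULL = observed)
predict_mediators_at <- function(model, data, level) {
  n <- length(data$sample_ids)
  parts <- list()
  if (model$edge_mask[["T->M"]]) {
    parts$t <- if (is.null(level)) {
      encode_design(model$treatment_spec, data$treatments)
    } else {
      constant_treatment_matrix(model, level, n)
    }
  }
  parts$x <- encode_design(model$pretreatment_spec, data$pretreatment)
  M <- predict(model$mediator_fit, bind_design(parts, n))
  colnames(M) <- model$mediator_names
  M
}

# predicted outcomes at a constant treatment level with supplied mediators
predict_outcomes_at <- function(model, data, level, M) {
  n <- length(data$sample_ids)
  parts <- list()
  if (model$edge_mask[["T->Y"]]) {
    parts$t <- if (is.null(level)) {
      encode_design(model$treatment_spec, data$treatments)
    } else {
      constant_treatment_matrix(model, level, n)
    }
  }
  if (model$edge_mask[["M->Y"]]) {
    m <- as.matrix(M)
    colnames(m) <- model$mediator_names
    parts$m <- m
  }
  parts$x <- encode_design(model$pretreatment_spec, data$pretreatment)
  predict(model$outcome_fit, bind_design(parts, n))
}

resolve_contrasts <- function(model, contrast) {
  if (is.null(contrast)) {
    lev <- treatment_levels(model)
    lapply(lev[-1], function(l) c(l, lev[1]))
  } else if (is.list(contrast)) {
    contrast
  } else {
    list(contrast)
  }
}

effect_table <- function(rows, scale) {
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  class(df) <- c("effect_table", "data.frame")
  attr(df, "scale") <- scale
  df
}

outcome_scale <- function(model) {
  if (model$outcome_family$name == "lnm") "relative_abundance_difference" else "response"
}

#' Estimate direct effects
#'
#' The direct effect of treatment level `a` versus `b` on each outcome is the
#' average plug-in contrast
#' `1/2 * sum_{t' in {a, b}} mean_i [Yhat_i(a, Mhat_i(t')) - Yhat_i(b, Mhat_i(t'))]`:
#' the change in the outcome when flipping the treatment on the direct path
#' while mediators are held at their counterfactual values, averaged over the
#' two mediator regimes.  The two per-regime components are retained (they
#' can differ under nonlinear models).
#'
#' @param model a fitted `mediation_model`.
#' @param data the [mediation_data()].
#' @param contrast `c(a, b)` naming two treatment levels ("a vs b"), a list
#'   of such pairs, or `NULL` for all levels versus the reference.
#' @return an `effect_table` data.frame with one row per outcome and contrast:
#'   columns `outcome`, `contrast`, `effect_type`, `component_1`,
#'   `component_2`, `estimate` (the mean of the two components).
#' @export
direct_effect <- function(model, data, contrast = NULL) {
  check_fitted(model)
  rows <- lapply(resolve_contrasts(model, contrast), function(cn) {
    a <- cn[1]; b <- cn[2]
    comp <- lapply(c(a, b), function(tp) {
      M <- predict_mediators_at(model, data, tp)
      colMeans(predict_outcomes_at(model, data, a, M) -
                 predict_outcomes_at(model, data, b, M))
    })
    data.frame(outcome = model$outcome_names,
               contrast = paste(a, "vs", b),
               effect_type = "direct",
               component_1 = comp[[1]], component_2 = comp[[2]],
               estimate = (comp[[1]] + comp[[2]]) / 2)
  })
  effect_table(rows, outcome_scale(model))
}

#' Estimate overall indirect effects
#'
#' The overall indirect effect of `a` versus `b` on each outcome is
#' `1/2 * sum_{t in {a, b}} mean_i [Yhat_i(t, Mhat_i(a)) - Yhat_i(t, Mhat_i(b))]`:
#' the change transmitted through all mediators jointly when they move from
#' their `b`-counterfactual to their `a`-counterfactual values, with the
#' direct path held fixed, averaged over the two direct-path regimes.
#'
#' @inheritParams direct_effect
#' @return an `effect_table` with one row per outcome and contrast.
#' @export
indirect_overall <- function(model, data, contrast = NULL) {
  check_fitted(model)
  rows <- lapply(resolve_contrasts(model, contrast), function(cn) {
    a <- cn[1]; b <- cn[2]
    Ma <- predict_mediators_at(model, data, a)
    Mb <- predict_mediators_at(model, data, b)
    comp <- lapply(c(a, b), function(t) {
      colMeans(predict_outcomes_at(model, data, t, Ma) -
                 predict_outcomes_at(model, data, t, Mb))
    })
    data.frame(outcome = model$outcome_names,
               contrast = paste(a, "vs", b),
               effect_type = "indirect_overall",
               component_1 = comp[[1]], component_2 = comp[[2]],
               estimate = (comp[[1]] + comp[[2]]) / 2)
  })
  effect_table(rows, outcome_scale(model))
}

#' Estimate pathwise indirect effects per mediator-outcome pair
#'
#' The pathwise indirect effect through mediator `k` moves only that
#' mediator between its `a` and `b` counterfactual values while the other
#' mediators stay at their `t'` counterfactuals:
#' `1/2 * sum_{t' in {a, b}} mean_i [Yhat_i(t', Mhat_ik(a), Mhat_i,-k(t')) -
#'  Yhat_i(t', Mhat_ik(b), Mhat_i,-k(t'))]`.
#' With an additive linear outcome model the pathwise effects sum to the
#' overall indirect effect.
#'
#' @inheritParams direct_effect
#' @return an `effect_table` with one row per outcome x mediator x contrast;
#'   includes a `mediator` column.
#' @export
indirect_pathwise <- function(model, data, contrast = NULL) {
  check_fitted(model)
  K <- length(model$mediator_names)
  rows <- lapply(resolve_contrasts(model, contrast), function(cn) {
    a <- cn[1]; b <- cn[2]
    Ma <- predict_mediators_at(model, data, a)
    Mb <- predict_mediators_at(model, data, b)
    out <- vector("list", K)
    comp1 <- comp2 <- matrix(0, K, length(model$outcome_names))
    for (tt in 1:2) {
      tp <- c(a, b)[tt]
      base <- if (tp == a) Ma else Mb
      for (k in seq_len(K)) {
        Mk_a <- base; Mk_a[, k] <- Ma[, k]
        Mk_b <- base; Mk_b[, k] <- Mb[, k]
        d <- colMeans(predict_outcomes_at(model, data, tp, Mk_a) -
                        predict_outcomes_at(model, data, tp, Mk_b))
        if (tt == 1) comp1[k, ] <- d else comp2[k, ] <- d
      }
    }
    for (k in seq_len(K)) {
      out[[k]] <- data.frame(outcome = model$outcome_names,
                             mediator = model$mediator_names[k],
                             contrast = paste(a, "vs", b),
                             effect_type = "indirect_pathwise",
                             component_1 = comp1[k, ], component_2 = comp2[k, ],
                             estimate = (comp1[k, ] + comp2[k, ]) / 2)
    }
    do.call(rbind, out)
  })
  effect_table(rows, outcome_scale(model))
}

#' Total effect of a contrast on each outcome
#'
#' `mean_i [Yhat_i(a, Mhat_i(a)) - Yhat_i(b, Mhat_i(b))]`; identically equal
#' to direct + overall indirect for any model family.
#'
#' @inheritParams direct_effect
#' @return an `effect_table` with one row per outcome and contrast.
#' @export
total_effect <- function(model, data, contrast = NULL) {
  check_fitted(model)
  rows <- lapply(resolve_contrasts(model, contrast), function(cn) {
    a <- cn[1]; b <- cn[2]
    ya <- predict_outcomes_at(model, data, a, predict_mediators_at(model, data, a))
    yb <- predict_outcomes_at(model, data, b, predict_mediators_at(model, data, b))
    est <- colMeans(ya - yb)
    data.frame(outcome = model$outcome_names, contrast = paste(a, "vs", b),
               effect_type = "total", component_1 = est, component_2 = est,
               estimate = est)
  })
  effect_table(rows, outcome_scale(model))
}

#' Write an effect table to tidy CSV
#' @param x an `effect_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_effects <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
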