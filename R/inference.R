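#' Percentile bootstrap over refitted mediation models
#'
#' Resamples the n samples jointly (rows of treatment, mediators, outcomes,
#' and covariates) with replacement, refits both submodels on each resample,
#' and evaluates every statistic function.  Confidence intervals are
#' percentile intervals of the replicate distribution; the inner 66%
#' interval is reported alongside, and the replicate matrix is returned so
#' the bootstrap histogram can be inspected before trusting the intervals.
#' Resampling is unstratified by default; `stratify = TRUE` resamples within
#' treatment arms (useful when an arm is tiny).
#'
#' @param model a fitted `mediation_model`.
#' @param data the [mediation_data()] the model was fitted on.
#' @param stat_fns named list of functions `(model, data) -> named numeric`.
#' @param B number of bootstrap replicates.
#' @param seed integer seed (required).
#' @param alpha interval level (default 0.05 for 95% intervals).
#' @param stratify resample within levels of the first treatment column.
#' @return object of class `bootstrap_result`: `replicates` (B_ok x
#'   n_statistics matrix), `point` (statistics on the original data), `ci`
#'   (data.frame with lower/upper and inner-66% bounds), `failures`
#'   (dropped replicate count), `B`, `alpha`.
#' @export
bootstrap <- function(model, data, stat_fns, B = 1000, seed, alpha = 0.05,
                      stratify = FALSE) {
  check_fitted(model)
  if (B < 1) abort("B must be >= 1", "medipath_value_error")
  if (!is.list(stat_fns)) stat_fns <- list(stat = stat_fns)
  if (is.null(names(stat_fns)) || any(!nzchar(names(stat_fns)))) {
    names(stat_fns) <- paste0("stat", seq_along(stat_fns))
  }
  eval_stats <- function(m, d) {
    out <- unlist(lapply(names(stat_fns), function(nm) {
      v <- stat_fns[[nm]](m, d)
      names(v) <- if (is.null(names(v))) {
        if (length(v) == 1) nm else paste0(nm, seq_along(v))
      } else {
        paste0(nm, ".", names(v))
      }
      v
    }))
    out
  }
  point <- eval_stats(model, data)
  n <- n_samples(data)
  arms <- if (stratify) split(seq_len(n), data$treatments[[1]]) else NULL

  reps <- with_seed(seed, {
    out <- vector("list", B)
    fails <- 0L
    for (b in seq_len(B)) {
      idx <- if (stratify) {
        unlist(lapply(arms, function(a) a[sample.int(length(a), length(a),
                                                     replace = TRUE)]))
      } else {
        sample.int(n, n, replace = TRUE)
      }
      star <- resample_rows(data, idx)
      res <- tryCatch({
        m_b <- estimate(model, star)
        eval_stats(m_b, star)
      }, error = function(e) NULL)
      if (is.null(res)) fails <- fails + 1L else out[[b]] <- res
    }
    list(out = out, fails = fails)
  })
  if (reps$fails > 0.1 * B) {
    abort(sprintf("%d of %d bootstrap refits failed", reps$fails, B),
          "medipath_inference_error")
  }
  mat <- do.call(rbind, Filter(Negate(is.null), reps$out))
  qs <- apply(mat, 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2, 0.17, 0.83), names = FALSE)
  ci <- data.frame(statistic = colnames(mat), estimate = point[colnames(mat)],
                   lower = qs[1, ], upper = qs[2, ],
                   inner_lower = qs[3, ], inner_upper = qs[4, ])
  rownames(ci) <- NULL
  structure(list(replicates = mat, point = point, ci = ci,
                 failures = reps$fails, B = B, alpha = alpha),
            class = "bootstrap_result")
}

resample_rows <- function(data, idx) {
  structure(
    list(sample_ids = as.character(seq_along(idx)),
         treatments = data$treatments[idx, , drop = FALSE],
         mediators = data$mediators[idx, , drop = FALSE],
         outcomes = data$outcomes[idx, , drop = FALSE],
         pretreatment = data$pretreatment[idx, , drop = FALSE]),
    class = "mediation_data"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: B = %d (%d failed), %d statistic(s)\n",
              x$B, x$failures, ncol(x$replicates)))
  print(x$ci)
  invisible(x)
}

#' Remove a causal edge from a mediation model
#'
#' Returns an unfitted copy of the model with one of the edges `T->M`,
#' `T->Y`, or `M->Y` removed from its design; re-estimate on data to obtain
#' the nullified fit.  Estimating after removing `T->Y` forces all direct
#' effects to zero; removing `T->M` or `M->Y` forces all indirect effects to
#' zero.  Nullified models are the synthetic-null generators for FDR
#' calibration.
#'
#' @param model a `mediation_model`.
#' @param edge one of `"T->M"`, `"T->Y"`, `"M->Y"`.
#' @return an unfitted `mediation_model` with the edge masked.
#' @export
nullify <- function(model, edge) {
  stopifnot(inherits(model, "mediation_model"))
  if (!edge %in% names(model$edge_mask)) {
    abort(sprintf("unknown edge '%s'; use one of %s", edge,
                  paste(names(model$edge_mask), collapse = ", ")),
          "medipath_value_error")
  }
  model$edge_mask[[edge]] <- FALSE
  model$mediator_fit <- NULL
  model$outcome_fit <- NULL
  model
}

#' Simulate a synthetic-null dataset from a fitted (masked) model
#'
#' Keeps the original pretreatment covariates and treatment assignments and
#' replaces mediators and outcomes with ancestral draws from the fitted
#' null model.  Effect estimates computed on the result act as negative
#' controls in [fdr_summary()].
#'
#' @param null_model a fitted `mediation_model`, typically after [nullify()]
#'   and [estimate()].
#' @param data the original [mediation_data()].
#' @param seed integer seed (required).
#' @param ... passed to the outcome sampler (e.g. `depths`).
#' @return a [mediation_data()] with simulated mediator and outcome blocks.
#' @export
synthetic_null_data <- function(null_model, data, seed, ...) {
  check_fitted(null_model)
  draw <- sample_counterfactual(null_model, data, prof = NULL, seed = seed, ...)
  out <- data
  out$mediators <- draw$mediators
  out$outcomes <- draw$outcomes
  out
}

#' Synthetic-null false discovery rate calibration
#'
#' Given matched per-feature statistics from the real data (`real_stats`)
#' and from a synthetic-null dataset (`null_stats`), estimates, for every
#' candidate threshold t (the pooled sorted unique absolute values),
#' `FDR(t) = #{d : |null_d| > t} / (#{d : |null_d| > t} + #{d : |real_d| > t})`
#' with 0/0 taken as 0 and strict inequalities throughout.  The selection
#' threshold is `t* = min{t : FDR(t) <= q}`; features with `|real_d| > t*`
#' are selected.  The per-feature `fdr_at_stat` column reports a monotone
#' (running-minimum from the largest threshold down) version of the curve,
#' akin to a q-value; raw values are in the `thresholds` attribute.
#'
#' @param real_stats numeric vector of length D.
#' @param null_stats numeric vector of length D (matched features).
#' @param q target FDR level in (0, 1).
#' @param feature_names optional feature labels.
#' @return object of class `fdr_table`: data.frame with `feature`,
#'   `real_stat`, `null_stat`, `fdr_at_stat`, `selected`; attributes
#'   `t_star`, `q`, `thresholds` (candidate grid with raw and monotone FDR).
#' @export
fdr_summary <- function(real_stats, null_stats, q = 0.15,
                        feature_names = NULL) {
  if (length(real_stats) != length(null_stats)) {
    abort("real and null statistic vectors must have equal length",
          "medipath_dim_error")
  }
  if (q <= 0 || q >= 1) abort("q must be in (0, 1)", "medipath_value_error")
  D <- length(real_stats)
  if (is.null(feature_names)) {
    feature_names <- names(real_stats) %||% paste0("feature", seq_len(D))
  }
  a_real <- abs(real_stats)
  a_null <- abs(null_stats)
  cand <- sort(unique(c(a_real, a_null)))
  n_null <- vapply(cand, function(t) sum(a_null > t), numeric(1))
  n_real <- vapply(cand, function(t) sum(a_real > t), numeric(1))
  denom <- n_null + n_real
  fdr_raw <- ifelse(denom == 0, 0, n_null / denom)
  fdr_mono <- rev(cummin(rev(fdr_raw)))
  ok <- which(fdr_raw <= q)
  t_star <- if (length(ok)) cand[min(ok)] else Inf
  selected <- a_real > t_star
  # per-feature monotone FDR at the feature's own statistic value
  fdr_at <- vapply(a_real, function(v) {
    i <- findInterval(v, cand)     # largest candidate <= v; v is in cand
    if (i == 0) fdr_mono[1] else fdr_mono[i]
  }, numeric(1))
  tab <- data.frame(feature = feature_names, real_stat = real_stats,
                    null_stat = null_stats, fdr_at_stat = fdr_at,
                    selected = selected)
  rownames(tab) <- NULL
  structure(tab, class = c("fdr_table", "data.frame"),
            t_star = t_star, q = q,
            thresholds = data.frame(threshold = cand, fdr_raw = fdr_raw,
                                    fdr_monotone = fdr_mono))
}

#' @export
print.fdr_table <- function(x, ...) {
  cat(sprintf("fdr_table: %d features, %d selected at q = %.2f (t* = %.4g)\n",
              nrow(x), sum(x$selected), attr(x, "q"), attr(x, "t_star")))
  invisible(x)
}
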