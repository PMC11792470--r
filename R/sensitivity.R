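#' Configuration for correlated-noise sensitivity analysis
#'
#' @param rho_grid numeric grid of confounding correlations in (-1, 1); 0 is
#'   always included as the anchor.
#' @param G mediator-outcome pairs subject to confounding: a two-column
#'   matrix/data.frame of (mediator, outcome) names or indices.  Keep G
#'   small; diffuse confounding patterns are rarely plausible.
#' @param n_reps simulated datasets per grid point.
#' @param seed integer seed (required at run time).
#' @param contrast contrast passed to the effect estimators (`NULL` = all
#'   levels vs reference).
#' @return a `sensitivity_config` list.
#' @export
sensitivity_config <- function(rho_grid = seq(-0.9, 0.9, by = 0.1), G,
                               n_reps = 20, seed = NULL, contrast = NULL) {
  if (any(abs(rho_grid) >= 1)) {
    abort("rho values must satisfy |rho| < 1", "medipath_value_error")
  }
  structure(list(rho_grid = sort(unique(c(0, rho_grid))), G = G,
                 n_reps = n_reps, seed = seed, contrast = contrast),
            class = "sensitivity_config")
}

resolve_pairs <- function(model, G) {
  G <- as.matrix(as.data.frame(G))
  if (ncol(G) != 2 || nrow(G) == 0) {
    abort("G must be a non-empty two-column (mediator, outcome) set",
          "medipath_value_error")
  }
  med <- model$mediator_names
  out <- model$outcome_names
  to_idx <- function(v, names) {
    nv <- suppressWarnings(as.numeric(v))
    if (!anyNA(nv)) as.integer(nv) else match(as.character(v), names)
  }
  ki <- to_idx(G[, 1], med)
  ji <- to_idx(G[, 2], out)
  if (anyNA(ki) || any(ki < 1) || any(ki > length(med)) ||
      anyNA(ji) || any(ji < 1) || any(ji > length(out))) {
    abort("G references unknown mediators or outcomes", "medipath_value_error")
  }
  cbind(mediator = ki, outcome = ji)
}

#' Build the confounding covariance Sigma(rho, G)
#'
#' Assembles the (K+J) x (K+J) joint covariance of the mediator and outcome
#' noise used in sensitivity simulation: `diag(sigma_M^2)` and
#' `diag(sigma_Y^2)` on the diagonal blocks and
#' `rho * sigma_M sigma_Y' (elementwise-masked by the pair indicator 1_G)`
#' off the diagonal.  Residual scales come from the fitted submodels.  The
#' result must be positive semidefinite; offending (rho, G) combinations are
#' rejected with a diagnostic.
#'
#' @param model a fitted `mediation_model`.
#' @param rho correlation in (-1, 1).
#' @param G mediator-outcome pair set (see [sensitivity_config()]).
#' @return covariance matrix of dimension (K+J).
#' @export
build_sigma_rho <- function(model, rho, G) {
  check_fitted(model)
  if (abs(rho) >= 1) abort("|rho| must be < 1", "medipath_value_error")
  sM <- unname(residual_scale(model$mediator_fit))
  sY <- unname(residual_scale(model$outcome_fit))
  K <- length(sM); J <- length(sY)
  mask <- matrix(0, K, J)
  pairs <- resolve_pairs(model, G)
  mask[pairs] <- 1
  off <- rho * (sM %o% sY) * mask
  Sigma <- rbind(cbind(diag(sM^2, K), off),
                 cbind(t(off), diag(sY^2, J)))
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    abort(sprintf(
      "Sigma(rho = %.3g) with %d confounded pair(s) is not positive semidefinite",
      rho, nrow(pairs)), "medipath_psd_error")
  }
  Sigma
}

check_sensitivity_family <- function(model) {
  ok <- c("linear", "regularized_l1", "regularized_l2", "random_forest")
  for (side in c("mediator_family", "outcome_family")) {
    nm <- model[[side]]$name
    if (!nm %in% ok) {
      abort(sprintf(
        "family '%s' lacks additive Gaussian residuals; correlated-noise sensitivity is unavailable",
        nm), "medipath_capability_error")
    }
  }
}

# one sweep over a grid of covariances; recompute_fn maps a refitted model
# and dataset to a named numeric vector of effects
sensitivity_sweep <- function(model, data, sigmas, grid_values, grid_name,
                              n_reps, seed, recompute_fn) {
  check_fitted(model)
  K <- length(model$mediator_names)
  J <- length(model$outcome_names)
  n <- n_samples(data)
  Mhat <- predict_mediators_at(model, data, level = NULL)
  rows <- list()
  reps_store <- list()
  with_seed(seed, {
    for (g in seq_along(sigmas)) {
      Sigma <- sigmas[[g]]
      reps <- matrix(NA_real_, n_reps, 0)
      est <- NULL
      for (r in seq_len(n_reps)) {
        eps <- MASS::mvrnorm(n, mu = rep(0, K + J), Sigma = Sigma)
        eps <- matrix(eps, nrow = n)
        Mstar <- Mhat + eps[, seq_len(K), drop = FALSE]
        od <- outcome_design(model, data$treatments, Mstar, data$pretreatment)
        Ystar <- predict(model$outcome_fit, od) +
          eps[, K + seq_len(J), drop = FALSE]
        star <- data
        star$mediators <- Mstar
        colnames(star$mediators) <- model$mediator_names
        star$outcomes <- Ystar
        colnames(star$outcomes) <- model$outcome_names
        refit <- estimate(model, star)
        v <- recompute_fn(refit, star)
        if (is.null(est)) {
          est <- matrix(NA_real_, n_reps, length(v),
                        dimnames = list(NULL, names(v)))
        }
        est[r, ] <- v
      }
      rows[[g]] <- data.frame(
        grid = grid_values[g],
        effect = colnames(est),
        mean_effect = colMeans(est),
        se = apply(est, 2, stats::sd) / sqrt(n_reps)
      )
      names(rows[[g]])[1] <- grid_name
      reps_store[[g]] <- est
    }
  })
  curve <- do.call(rbind, rows)
  rownames(curve) <- NULL
  anchor <- curve[curve[[grid_name]] == 0, c("effect", "mean_effect")]
  curve$sign_flipped <- sign(curve$mean_effect) !=
    sign(anchor$mean_effect[match(curve$effect, anchor$effect)])
  structure(curve, class = c("sensitivity_curve", "data.frame"),
            replicates = reps_store, grid_name = grid_name)
}

#' Sensitivity of overall indirect effects to mediator-outcome confounding
#'
#' For each correlation rho on the grid, draws correlated mediator and
#' outcome noise `(eps_m, eps_y) ~ N(0, Sigma(rho, G))`, forms perturbed data
#' `M* = Mhat(T_obs) + eps_m` and `Y* = Yhat(T_obs, M*) + eps_y`, refits both
#' submodels, and recomputes the overall indirect effect.  Confounding (rho
#' != 0) biases the refitted mediator-outcome association, so the curve shows
#' how strongly the unconfoundedness assumption carries the original
#' estimate.  A sign flip at small |rho| marks a fragile estimate.  Requires
#' additive-Gaussian-residual families on both sides.
#'
#' @param model a fitted `mediation_model`.
#' @param data the [mediation_data()].
#' @param config a [sensitivity_config()].
#' @return a `sensitivity_curve` data.frame: one row per (rho, effect) with
#'   `mean_effect`, `se` over replicates, and `sign_flipped` relative to the
#'   rho = 0 anchor.  Per-replicate estimates are in the `replicates`
#'   attribute.  Non-PSD grid points are dropped with a warning.
#' @export
sensitivity <- function(model, data, config) {
  check_sensitivity_family(model)
  sw <- build_grid_sigmas(model, config)
  sensitivity_sweep(
    model, data, sw$sigmas, sw$values, "rho",
    config$n_reps, config$seed,
    function(m, d) {
      et <- indirect_overall(m, d, config$contrast)
      stats::setNames(et$estimate, paste0(et$outcome, "|", et$contrast))
    }
  )
}

build_grid_sigmas <- function(model, config) {
  sigmas <- list(); values <- numeric()
  for (rho in config$rho_grid) {
    S <- tryCatch(build_sigma_rho(model, rho, config$G), error = function(e) e)
    if (inherits(S, "error")) {
      warning(sprintf("dropping rho = %.3g: %s", rho, conditionMessage(S)),
              call. = FALSE)
    } else {
      sigmas <- c(sigmas, list(S)); values <- c(values, rho)
    }
  }
  if (!0 %in% values) abort("the rho = 0 anchor was rejected", "medipath_psd_error")
  list(sigmas = sigmas, values = values)
}

#' Sensitivity of pathwise indirect effects
#'
#' As [sensitivity()], but recomputes pathwise indirect effects restricted to
#' the requested mediator-outcome pairs; `G` defaults to those same pairs.
#'
#' @inheritParams sensitivity
#' @param pairs two-column (mediator, outcome) set of pathwise effects to
#'   track; defaults to `config$G`.
#' @return a `sensitivity_curve` with one trajectory per pair.
#' @export
sensitivity_pathwise <- function(model, data, config, pairs = NULL) {
  check_sensitivity_family(model)
  if (is.null(pairs)) pairs <- config$G
  idx <- resolve_pairs(model, pairs)
  med <- model$mediator_names[idx[, 1]]
  out <- model$outcome_names[idx[, 2]]
  sw <- build_grid_sigmas(model, config)
  sensitivity_sweep(
    model, data, sw$sigmas, sw$values, "rho",
    config$n_reps, config$seed,
    function(m, d) {
      et <- indirect_pathwise(m, d, config$contrast)
      key <- paste0(et$mediator, "|", et$outcome)
      want <- paste0(med, "|", out)
      sel <- et[key %in% want, ]
      stats::setNames(sel$estimate,
                      paste0(sel$mediator, "->", sel$outcome, "|", sel$contrast))
    }
  )
}

#' Sensitivity under a user-supplied covariance perturbation
#'
#' Sweeps `Sigma(Delta, nu) = diag(c(sigma_M^2, sigma_Y^2)) + nu * Delta`
#' over the `nu_grid`, allowing arbitrary confounding patterns (including
#' cross-mediator correlation, which leaves linear-additive indirect
#' estimates unbiased in expectation).  Non-PSD grid points are rejected.
#'
#' @inheritParams sensitivity
#' @param Delta symmetric (K+J) x (K+J) perturbation matrix.
#' @param nu_grid nonnegative scaling grid; 0 is always included.
#' @param n_reps replicates per grid point.
#' @param seed integer seed.
#' @param contrast passed to [indirect_overall()].
#' @return a `sensitivity_curve` over `nu`.
#' @export
sensitivity_perturb <- function(model, data, Delta, nu_grid, n_reps = 20,
                                seed, contrast = NULL) {
  check_sensitivity_family(model)
  check_fitted(model)
  Delta <- as.matrix(Delta)
  if (!isSymmetric(unname(Delta), tol = 1e-10)) {
    abort("Delta must be symmetric", "medipath_value_error")
  }
  sM <- unname(residual_scale(model$mediator_fit))
  sY <- unname(residual_scale(model$outcome_fit))
  base <- diag(c(sM^2, sY^2))
  if (!all(dim(Delta) == dim(base))) {
    abort("Delta dimension must be (K+J) x (K+J)", "medipath_dim_error")
  }
  nu_grid <- sort(unique(c(0, nu_grid)))
  sigmas <- list(); values <- numeric()
  for (nu in nu_grid) {
    S <- base + nu * Delta
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev))) {
      warning(sprintf("dropping nu = %.3g: Sigma not positive semidefinite", nu),
              call. = FALSE)
    } else {
      sigmas <- c(sigmas, list(S)); values <- c(values, nu)
    }
  }
  sensitivity_sweep(
    model, data, sigmas, values, "nu", n_reps, seed,
    function(m, d) {
      et <- indirect_overall(m, d, contrast)
      stats::setNames(et$estimate, paste0(et$outcome, "|", et$contrast))
    }
  )
}

#' Write a sensitivity curve to tidy CSV
#' @param x a `sensitivity_curve`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sensitivity <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
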