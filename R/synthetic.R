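#' Specification for a synthetic mediation experiment
#'
#' Describes an ancestral generative model `X -> T -> M -> Y` with known
#' coefficients, so that simulated data come with closed-form ground-truth
#' effects: for a Gaussian outcome and a contrast whose treatment scores
#' differ by `d`, the true overall indirect effect on outcome j is
#' `d * sum_k alpha_k beta_kj`, the true direct effect is `d * gamma_j`, and
#' the true pathwise effect through mediator k is `d * alpha_k beta_kj`.
#'
#' @param n sample count.
#' @param treatment list describing the assignment: `kind` is `"binary"`
#'   (levels control/treated with probability `p` of treatment, scores 0/1),
#'   `"multilevel"` (`levels` labels with `scores`, default 0..L-1, and
#'   assignment `probs`), or `"continuous"` (standard normal dose).
#' @param K,J,P mediator, outcome, and covariate counts.
#' @param alpha length-K treatment-to-mediator coefficients.
#' @param beta K x J mediator-to-outcome coefficient matrix.
#' @param gamma length-J direct treatment-to-outcome coefficients.
#' @param noise_sd_M,noise_sd_Y noise scales (scalar or per-column).
#' @param outcome_kind `"gaussian"`, `"compositional"` (latent Gaussian
#'   predictor mapped through [phi_inverse()] and drawn as multinomial counts
#'   at Poisson depths), or `"zero_inflated"` (Bernoulli presence times a
#'   lognormal magnitude).
#' @param depth_mean mean sequencing depth for compositional outcomes.
#' @param zero_prob baseline absence probability for zero-inflated outcomes.
#' @param confounder_rho optional list `(rho, G)` injecting true
#'   mediator-outcome noise correlation (unmeasured confounding); `G` is a
#'   two-column (mediator, outcome) index set.
#' @param seed integer seed (required at simulation time).
#' @return a `simulation_spec` list.
#' @export
simulation_spec <- function(n, treatment = list(kind = "binary", p = 0.5),
                            K = 1, J = 1, P = 0,
                            alpha = rep(0, K), beta = matrix(0, K, J),
                            gamma = rep(0, J),
                            noise_sd_M = 1, noise_sd_Y = 1,
                            outcome_kind = c("gaussian", "compositional",
                                             "zero_inflated"),
                            depth_mean = 5000, zero_prob = 0.3,
                            confounder_rho = NULL, seed = NULL) {
  outcome_kind <- match.arg(outcome_kind)
  beta <- matrix(beta, K, J)
  if (length(alpha) != K || nrow(beta) != K || ncol(beta) != J ||
      length(gamma) != J) {
    abort("alpha/beta/gamma dimensions are inconsistent with K and J",
          "medipath_spec_error")
  }
  if (n < 2 || K < 1 || J < 1 || P < 0) {
    abort("invalid dimensions in simulation spec", "medipath_spec_error")
  }
  structure(list(n = n, treatment = treatment, K = K, J = J, P = P,
                 alpha = alpha, beta = beta, gamma = gamma,
                 noise_sd_M = rep_len(noise_sd_M, K),
                 noise_sd_Y = rep_len(noise_sd_Y, J),
                 outcome_kind = outcome_kind, depth_mean = depth_mean,
                 zero_prob = zero_prob, confounder_rho = confounder_rho,
                 seed = seed),
            class = "simulation_spec")
}

truth_table <- function(spec, contrast_label, d = 1) {
  med <- paste0("M", seq_len(spec$K))
  out <- paste0("Y", seq_len(spec$J))
  delta <- d * as.numeric(crossprod(spec$alpha, spec$beta))
  zeta <- d * spec$gamma
  rows <- list(
    data.frame(outcome = out, mediator = NA_character_,
               contrast = contrast_label, effect_type = "indirect_overall",
               estimate = delta),
    data.frame(outcome = out, mediator = NA_character_,
               contrast = contrast_label, effect_type = "direct",
               estimate = zeta)
  )
  pw <- expand.grid(mediator = seq_len(spec$K), outcome = seq_len(spec$J))
  rows[[3]] <- data.frame(
    outcome = out[pw$outcome], mediator = med[pw$mediator],
    contrast = contrast_label, effect_type = "indirect_pathwise",
    estimate = d * spec$alpha[pw$mediator] * spec$beta[cbind(pw$mediator, pw$outcome)]
  )
  tt <- do.call(rbind, rows)
  rownames(tt) <- NULL
  class(tt) <- c("effect_table", "data.frame")
  attr(tt, "scale") <- if (spec$outcome_kind == "gaussian") "response" else "latent"
  tt
}

#' Simulate a mediation dataset with known ground truth
#'
#' Ancestral draw `X -> T -> M -> Y` per the spec.  Compositional outcomes
#' pass the Gaussian linear predictor (dimension J-1) through
#' [phi_inverse()] and draw multinomial counts at Poisson-distributed
#' depths; zero-inflated outcomes multiply a Bernoulli presence layer into a
#' lognormal magnitude.  The returned truth table is exact on the response
#' scale for Gaussian outcomes and on the latent scale otherwise.
#'
#' @param spec a [simulation_spec()].
#' @return list with `data` (a [mediation_data()]) and `truth` (an
#'   `effect_table` of true effects for the treated-vs-reference contrast).
#' @export
simulate_mediation <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  with_seed(spec$seed, {
    n <- spec$n; K <- spec$K; J <- spec$J; P <- spec$P
    X <- if (P > 0) {
      matrix(stats::rnorm(n * P), n, P,
             dimnames = list(NULL, paste0("X", seq_len(P))))
    } else {
      NULL
    }
    tr <- spec$treatment
    kind <- tr$kind %||% "binary"
    if (kind == "binary") {
      lev <- c("control", "treated")
      tl <- lev[1 + stats::rbinom(n, 1, tr$p %||% 0.5)]
      dose <- as.numeric(tl == "treated")
      t_col <- tl
      contrast_label <- "treated vs control"
      d_contrast <- 1
    } else if (kind == "multilevel") {
      lev <- tr$levels %||% paste0("level", seq_len(tr$L %||% 3))
      scores <- tr$scores %||% (seq_along(lev) - 1)
      probs <- tr$probs %||% rep(1 / length(lev), length(lev))
      tl <- sample(lev, n, replace = TRUE, prob = probs)
      dose <- scores[match(tl, lev)]
      t_col <- tl
      contrast_label <- paste(lev[2], "vs", lev[1])
      d_contrast <- scores[2] - scores[1]
    } else {
      dose <- stats::rnorm(n)
      t_col <- dose
      contrast_label <- "1 vs 0"
      d_contrast <- 1
    }

    em <- matrix(stats::rnorm(n * K), n, K) %*% diag(spec$noise_sd_M, K)
    ey <- matrix(stats::rnorm(n * J), n, J) %*% diag(spec$noise_sd_Y, J)
    if (!is.null(spec$confounder_rho)) {
      Sigma <- confounder_sigma(spec)
      eps <- MASS::mvrnorm(n, rep(0, K + J), Sigma)
      eps <- matrix(eps, nrow = n)
      em <- eps[, seq_len(K), drop = FALSE]
      ey <- eps[, K + seq_len(J), drop = FALSE]
    }

    M <- outer(dose, spec$alpha) + em
    colnames(M) <- paste0("M", seq_len(K))
    eta <- outer(dose, spec$gamma) + M %*% spec$beta

    if (spec$outcome_kind == "gaussian") {
      Y <- eta + ey
    } else if (spec$outcome_kind == "compositional") {
      if (J < 2) abort("compositional outcomes need J >= 2", "medipath_spec_error")
      latent <- (eta + ey)[, seq_len(J - 1), drop = FALSE]
      Pm <- phi_inverse(latent)
      depths <- stats::rpois(n, spec$depth_mean)
      depths[depths == 0] <- 1
      Y <- t(vapply(seq_len(n),
                    function(i) as.numeric(stats::rmultinom(1, depths[i], Pm[i, ])),
                    numeric(J)))
    } else {
      pres <- matrix(stats::rbinom(n * J, 1, 1 - spec$zero_prob), n, J)
      Y <- pres * exp(eta + ey)
    }
    colnames(Y) <- paste0("Y", seq_len(J))

    df <- data.frame(treat = t_col, check.names = FALSE)
    df <- cbind(df, as.data.frame(M), as.data.frame(Y))
    if (!is.null(X)) df <- cbind(df, as.data.frame(X))
    roles <- role_map("treat",
                      mediators = starts_with("M"),
                      outcomes = starts_with("Y"),
                      pretreatment = if (P > 0) paste0("X", seq_len(P)) else character())
    data <- mediation_data(df, roles)
    list(data = data, truth = truth_table(spec, contrast_label, d_contrast))
  })
}

confounder_sigma <- function(spec) {
  K <- spec$K; J <- spec$J
  mask <- matrix(0, K, J)
  G <- as.matrix(as.data.frame(spec$confounder_rho$G))
  mask[G] <- 1
  off <- spec$confounder_rho$rho * (spec$noise_sd_M %o% spec$noise_sd_Y) * mask
  Sigma <- rbind(cbind(diag(spec$noise_sd_M^2, K), off),
                 cbind(t(off), diag(spec$noise_sd_Y^2, J)))
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    abort("confounder_rho implies a non-PSD noise covariance", "medipath_psd_error")
  }
  Sigma
}

#' Small deterministic fixtures with printed ground truth
#'
#' Named toy experiments reused across examples and tests:
#' * `"chain"`: one mediator, one outcome, `M = 2T + e`, `Y = 3M + 1T + e`
#'   (unit noise) — truth (indirect, direct) = (6, 1);
#' * `"two_path"`: two mediators with `alpha = (2, -1)`, `beta = (3, 4)` —
#'   pathwise truths 6 and -4, overall indirect 2;
#' * `"null"`: all coefficients zero;
#' * `"compositional"`: five-taxon multinomial outcome at depths near 5000.
#'
#' @param name fixture name.
#' @param n sample count (default 100).
#' @param seed integer seed (default 1).
#' @return list with `data` and `truth`, as [simulate_mediation()].
#' @export
make_toy_fixture <- function(name = c("chain", "two_path", "null",
                                      "compositional"),
                             n = 100, seed = 1) {
  name <- tryCatch(match.arg(name),
                   error = function(e) abort(sprintf("unknown fixture '%s'", name[1]),
                                             "medipath_value_error"))
  spec <- switch(
    name,
    chain = simulation_spec(n, K = 1, J = 1, alpha = 2, beta = 3, gamma = 1,
                            seed = seed),
    two_path = simulation_spec(n, K = 2, J = 1, alpha = c(2, -1),
                               beta = matrix(c(3, 4), 2, 1), gamma = 0.5,
                               seed = seed),
    null = simulation_spec(n, K = 2, J = 3, seed = seed),
    compositional = simulation_spec(n, K = 1, J = 5, alpha = 1.5,
                                    beta = matrix(c(1, -1, 0.5, 0, 0.25), 1, 5),
                                    gamma = rep(0.2, 5),
                                    outcome_kind = "compositional",
                                    depth_mean = 5000, seed = seed)
  )
  simulate_mediation(spec)
}
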