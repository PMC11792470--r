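#' Construct a model family
#'
#' A model family is the contract every mediator or outcome regression must
#' satisfy so that families are interchangeable inside the mediation graph:
#' `fit` learns parameters from a design and a response matrix, `predict`
#' returns the expected response matrix for any design with the same columns,
#' `sample` draws a stochastic response matrix given a seed, and
#' `residual_scale` reports per-response noise scales used by the sensitivity
#' module.  The built-in constructors ([family_linear()],
#' [family_regularized()], [family_random_forest()], [family_lnm()],
#' [family_hurdle()]) all go through this constructor; users can register a
#' custom family the same way.
#'
#' @param name short family label.
#' @param fit function(design, responses, config) returning a parameter store.
#' @param predict function(params, design) returning an n x R matrix.
#' @param sample function(params, design, ...) returning a stochastic n x R
#'   matrix; called inside a seeded RNG context.
#' @param residual_scale function(params) returning a positive length-R vector.
#' @param config named list of family settings.
#' @return object of class `model_family`.
#' @export
model_family <- function(name, fit, predict, sample, residual_scale,
                         config = list()) {
  fam <- structure(
    list(name = name, fit = fit, predict = predict, sample = sample,
         residual_scale = residual_scale, config = config),
    class = "model_family"
  )
  check_family_contract(fam)
  fam
}

check_family_contract <- function(family) {
  if (!is.list(family)) {
    abort("a model family must be a list-like object", "medipath_contract_error")
  }
  for (cap in c("fit", "predict", "sample", "residual_scale")) {
    if (!is.function(family[[cap]])) {
      abort(sprintf("family '%s' is missing capability '%s'",
                    family$name %||% "?", cap),
            "medipath_contract_error")
    }
  }
  invisible(family)
}

#' @export
print.model_family <- function(x, ...) {
  cat(sprintf("model_family '%s'\n", x$name))
  invisible(x)
}

#' Fit a model family to a design and response matrix
#'
#' @param family a [model_family()].
#' @param design numeric matrix (n x D, no intercept column; families add
#'   their own intercept).  D may be 0 for intercept-only models.
#' @param responses numeric matrix n x R (column names become response names).
#' @return object of class `fitted_family`.
#' @export
fit_family <- function(family, design, responses) {
  check_family_contract(family)
  design <- as_design(design)
  responses <- as.matrix(responses)
  if (is.null(colnames(responses))) {
    colnames(responses) <- paste0("resp", seq_len(ncol(responses)))
  }
  if (nrow(design) != nrow(responses)) {
    abort("design and responses disagree on row count", "medipath_dim_error")
  }
  params <- family$fit(design, responses, family$config)
  structure(
    list(family = family, params = params,
         response_names = colnames(responses),
         design_names = colnames(design)),
    class = "fitted_family"
  )
}

as_design <- function(design) {
  design <- as.matrix(design)
  if (nrow(design) > 0 && ncol(design) > 0 && !is.numeric(design)) {
    abort("design matrix must be numeric", "medipath_type_error")
  }
  if (is.null(colnames(design)) && ncol(design) > 0) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  design
}

check_design_names <- function(object, design) {
  if (!identical(colnames(design), object$design_names)) {
    abort("design columns do not match the columns seen at fit time",
          "medipath_dim_error")
  }
}

#' @export
predict.fitted_family <- function(object, design, ...) {
  design <- as_design(design)
  check_design_names(object, design)
  out <- object$family$predict(object$params, design)
  colnames(out) <- object$response_names
  out
}

#' Draw a stochastic response matrix from a fitted family
#'
#' @param object a `fitted_family`.
#' @param design numeric design matrix with the training columns.
#' @param seed integer seed (required; no silent nondeterminism).
#' @param ... family-specific options (e.g. `depths` for count samplers).
#' @return n x R matrix of draws.
#' @export
sample_family <- function(object, design, seed, ...) {
  stopifnot(inherits(object, "fitted_family"))
  design <- as_design(design)
  check_design_names(object, design)
  out <- with_seed(seed, object$family$sample(object$params, design, ...))
  colnames(out) <- object$response_names
  out
}

#' Per-response residual noise scales of a fitted family
#' @param object a `fitted_family`.
#' @return positive numeric vector, one entry per response.
#' @export
residual_scale <- function(object) {
  stopifnot(inherits(object, "fitted_family"))
  out <- object$family$residual_scale(object$params)
  names(out) <- object$response_names
  out
}

#' @export
print.fitted_family <- function(x, ...) {
  cat(sprintf("fitted '%s' family: %d response(s), %d predictor(s)\n",
              x$family$name, length(x$response_names), length(x$design_names)))
  invisible(x)
}

## ---- ordinary least squares -------------------------------------------------

# multi-response OLS with minimum-norm fallback for rank-deficient designs
ols_fit <- function(X, Y) {
  qrx <- qr(X)
  r <- qrx$rank
  if (r < ncol(X)) {
    warning("rank-deficient design; using the minimum-norm solution",
            call. = FALSE)
    coef <- MASS::ginv(X) %*% Y
  } else {
    coef <- qr.coef(qrx, Y)
  }
  coef <- as.matrix(coef)
  fitted <- X %*% coef
  resid <- Y - fitted
  df <- max(nrow(X) - r, 1)
  sigma <- sqrt(colSums(resid^2) / df)
  list(coef = coef, sigma = sigma, rank = r)
}

#' Linear (ordinary least squares) model family
#'
#' One OLS regression per response.  Residual scales are per-response
#' residual standard deviations with denominator n - rank.
#'
#' @return a [model_family()].
#' @export
family_linear <- function() {
  model_family(
    name = "linear",
    fit = function(design, responses, config) {
      X <- cbind(`(Intercept)` = 1, design)
      c(ols_fit(X, responses), list(n = nrow(design)))
    },
    predict = function(params, design) {
      cbind(1, design) %*% params$coef
    },
    sample = function(params, design, ...) {
      mu <- cbind(1, design) %*% params$coef
      mu + matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)) %*%
        diag(params$sigma, ncol(mu))
    },
    residual_scale = function(params) params$sigma
  )
}

#' Convenience wrapper fitting the linear family
#' @param design numeric design matrix (no intercept column).
#' @param responses numeric response matrix.
#' @return a `fitted_family`.
#' @export
fit_linear <- function(design, responses) {
  fit_family(family_linear(), design, responses)
}

## ---- penalized linear (lasso / ridge) ---------------------------------------

# package lambda convention: minimize  RSS + lambda * ||beta||_1   (l1)
#                            or        RSS + lambda * ||beta||_2^2 (l2)
# with the intercept unpenalized; a single lambda is shared by all responses.
glmnet_lambda <- function(lambda, penalty, n) {
  if (penalty == "l1") lambda / (2 * n) else lambda / n
}

#' Penalized linear model family (lasso or ridge)
#'
#' Fits one penalized regression per response with a single penalty shared
#' across all responses.  The objective per response j is
#' `sum_i (y_ij - x_i' beta_j)^2 + lambda * P(beta_j)` with `P` the l1 norm or
#' the squared l2 norm and an unpenalized intercept.  `lambda = "auto"`
#' selects the shared penalty by 5-fold cross-validation on the squared error
#' pooled over all responses, with a fixed fold seed recorded in the fit.
#'
#' @param penalty `"l1"` (lasso) or `"l2"` (ridge).
#' @param lambda nonnegative penalty, or `"auto"`.
#' @param cv_folds folds for `"auto"` selection.
#' @param cv_seed fold-assignment seed for `"auto"` selection.
#' @param penalty_mask optional 0/1 vector over design columns; 0 exempts a
#'   column from the penalty (e.g. shrink only participant intercepts).
#' @return a [model_family()].
#' @export
family_regularized <- function(penalty = c("l1", "l2"), lambda = "auto",
                               cv_folds = 5, cv_seed = 1, penalty_mask = NULL) {
  penalty <- match.arg(penalty)
  if (is.numeric(lambda) && lambda < 0) {
    abort("lambda must be nonnegative", "medipath_value_error")
  }
  cfg <- list(penalty = penalty, lambda = lambda, cv_folds = cv_folds,
              cv_seed = cv_seed, penalty_mask = penalty_mask)
  model_family(
    name = paste0("regularized_", penalty),
    config = cfg,
    fit = function(design, responses, config) fit_glmnet_multi(design, responses, config),
    predict = function(params, design) {
      cbind(1, design[, params$keep, drop = FALSE]) %*% params$coef
    },
    sample = function(params, design, ...) {
      mu <- cbind(1, design[, params$keep, drop = FALSE]) %*% params$coef
      mu + matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)) %*%
        diag(params$sigma, ncol(mu))
    },
    residual_scale = function(params) params$sigma
  )
}

fit_glmnet_multi <- function(design, responses, config) {
  n <- nrow(responses)
  R <- ncol(responses)
  keep <- rep(TRUE, ncol(design))
  D <- ncol(design)
  alpha <- if (config$penalty == "l1") 1 else 0

  if (D == 0) {
    coef <- matrix(colMeans(responses), nrow = 1,
                   dimnames = list("(Intercept)", colnames(responses)))
    resid <- sweep(responses, 2, coef[1, ])
    return(list(coef = coef, sigma = sqrt(colSums(resid^2) / max(n - 1, 1)),
                keep = keep, lambda = 0))
  }

  # glmnet needs >= 2 predictors; pad with an all-zero column when D == 1
  pad <- D == 1
  X <- if (pad) cbind(design, `..pad..` = 0) else design
  pf <- rep(1, ncol(X))
  if (!is.null(config$penalty_mask)) {
    pf[seq_len(D)] <- ifelse(config$penalty_mask == 0, 0, 1)
  }

  lambda <- config$lambda
  if (identical(lambda, "auto")) {
    lambda <- select_lambda_cv(X, responses, alpha, pf, config)
  }
  gl <- glmnet_lambda(lambda, config$penalty, n)
  # descending warm-start path ending at the requested value
  path <- unique(sort(c(gl * c(100, 10, 2), gl,
                        max(gl, 1e-3) * c(50, 5)), decreasing = TRUE))
  coef <- matrix(0, D + 1, R,
                 dimnames = list(c("(Intercept)", colnames(design)),
                                 colnames(responses)))
  for (r in seq_len(R)) {
    fit <- glmnet::glmnet(X, responses[, r], alpha = alpha, lambda = path,
                          standardize = FALSE, penalty.factor = pf,
                          thresh = 1e-12)
    b <- as.numeric(stats::coef(fit, s = gl, exact = FALSE))
    coef[, r] <- b[seq_len(D + 1)]
  }
  fitted <- cbind(1, design) %*% coef
  resid <- responses - fitted
  df <- pmax(n - colSums(coef != 0), 1)
  list(coef = coef, sigma = sqrt(colSums(resid^2) / df), keep = keep,
       lambda = lambda)
}

# pooled-deviance cross-validation for the shared penalty
select_lambda_cv <- function(X, responses, alpha, pf, config) {
  n <- nrow(responses)
  sy <- scale(responses, scale = FALSE)
  lam_max <- max(abs(crossprod(X, sy))) / n
  if (!is.finite(lam_max) || lam_max <= 0) lam_max <- 1
  grid <- lam_max * 10^seq(0, -4, length.out = 30)  # glmnet scale
  folds <- with_seed(config$cv_seed,
                     sample(rep_len(seq_len(config$cv_folds), n)))
  err <- numeric(length(grid))
  for (f in seq_len(config$cv_folds)) {
    tr <- folds != f
    for (r in seq_len(ncol(responses))) {
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], responses[tr, r],
                            alpha = alpha, lambda = grid, standardize = FALSE,
                            penalty.factor = pf, thresh = 1e-9)
      pr <- stats::predict(fit, X[!tr, , drop = FALSE], s = grid)
      err <- err + colSums((responses[!tr, r] - pr)^2)
    }
  }
  gl <- grid[which.min(err)]
  # convert back to the package's raw-RSS lambda convention
  if (alpha == 1) gl * 2 * n else gl * n
}

#' Convenience wrapper fitting a penalized linear family
#' @inheritParams fit_linear
#' @param penalty `"l1"` or `"l2"`.
#' @param lambda nonnegative penalty or `"auto"`.
#' @param ... passed to [family_regularized()].
#' @return a `fitted_family`.
#' @export
fit_regularized <- function(design, responses, penalty = "l1",
                            lambda = "auto", ...) {
  fit_family(family_regularized(penalty = penalty, lambda = lambda, ...),
             design, responses)
}

## ---- random forest ----------------------------------------------------------

rf_predict <- function(params, design) {
  if (ncol(design) == 0) design <- cbind(`..const..` = rep(1, nrow(design)))
  df <- as.data.frame(design)
  names(df) <- paste0("V", seq_len(ncol(df)))
  out <- vapply(params$forests,
                function(f) stats::predict(f, data = df, num.threads = 1)$predictions,
                numeric(nrow(df)))
  matrix(out, nrow = nrow(df))
}

#' Random forest model family
#'
#' One regression forest per response (via ranger).  `predict` is the
#' ensemble mean; `sample` adds Gaussian noise at the residual scale, which is
#' estimated from out-of-bag residuals.  A seed is required: forests are
#' never silently nondeterministic.
#'
#' @param n_trees trees per forest.
#' @param seed integer seed for tree growing (required).
#' @param min_node_size minimal node size (1 grows to purity).
#' @return a [model_family()].
#' @export
family_random_forest <- function(n_trees = 500, seed = NULL, min_node_size = 5) {
  if (n_trees < 1) abort("n_trees must be >= 1", "medipath_value_error")
  if (is.null(seed)) {
    abort("family_random_forest requires an explicit seed", "medipath_value_error")
  }
  model_family(
    name = "random_forest",
    config = list(n_trees = n_trees, seed = seed, min_node_size = min_node_size),
    fit = function(design, responses, config) {
      if (ncol(design) == 0) {
        design <- cbind(`..const..` = rep(1, nrow(responses)))
      }
      df <- as.data.frame(design)
      names(df) <- paste0("V", seq_len(ncol(df)))
      forests <- vector("list", ncol(responses))
      sigma <- numeric(ncol(responses))
      for (r in seq_len(ncol(responses))) {
        df$.y <- responses[, r]
        forests[[r]] <- ranger::ranger(
          dependent.variable.name = ".y", data = df,
          num.trees = config$n_trees, min.node.size = config$min_node_size,
          seed = config$seed + r, num.threads = 1
        )
        oob <- forests[[r]]$predictions
        ok <- !is.na(oob)
        sigma[r] <- if (any(ok)) {
          sqrt(mean((responses[ok, r] - oob[ok])^2))
        } else {
          stats::sd(responses[, r])
        }
      }
      list(forests = forests, sigma = sigma, pad = ncol(design) == 1 &&
             colnames(design)[1] == "..const..")
    },
    predict = function(params, design) rf_predict(params, design),
    sample = function(params, design, ...) {
      mu <- rf_predict(params, design)
      mu + matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)) %*%
        diag(params$sigma, ncol(mu))
    },
    residual_scale = function(params) params$sigma
  )
}

#' Convenience wrapper fitting random forests
#' @inheritParams fit_linear
#' @param n_trees trees per forest.
#' @param seed integer seed (required).
#' @return a `fitted_family`.
#' @export
fit_random_forest <- function(design, responses, n_trees = 500, seed = NULL) {
  fit_family(family_random_forest(n_trees = n_trees, seed = seed),
             design, responses)
}

## ---- logistic-normal multinomial --------------------------------------------

#' Inverse additive logistic map onto the simplex
#'
#' Maps a length J-1 latent vector (or an n x (J-1) matrix, row-wise) to a
#' strictly positive composition summing to one; the last coordinate is the
#' reference category.  Computed in log space with max subtraction, so large
#' latent values saturate without overflow.
#'
#' @param mu numeric vector of length J-1 or matrix n x (J-1).
#' @return simplex vector of length J, or matrix n x J.
#' @examples
#' phi_inverse(c(0, 0, 0))        # uniform over 4 categories
#' phi_inverse(log(2))            # (2/3, 1/3)
#' @export
phi_inverse <- function(mu) {
  vec <- is.null(dim(mu))
  mu <- rbind(mu)
  if (any(!is.finite(mu))) abort("mu must be finite", "medipath_value_error")
  eta <- cbind(mu, 0)
  m <- apply(eta, 1, max)
  ex <- exp(eta - m)
  p <- ex / rowSums(ex)
  # deep saturation underflows to 0; clamp so the output stays strictly
  # positive (downstream log-ratios must never see an exact zero)
  p <- pmax(p, .Machine$double.xmin)
  if (vec) drop(p) else p
}

#' Logistic-normal multinomial model family (MAP estimate)
#'
#' Models an n x J count matrix as multinomial draws whose composition is the
#' inverse additive-logistic transform of a linear predictor:
#' `Y_i ~ Mult(N_i, phi_inverse(B z_i))` with `B` a (J-1) x D coefficient
#' matrix and independent Gaussian priors `b ~ N(0, prior_sigma2)` on every
#' entry.  The maximum a posteriori `B` is found by quasi-Newton (BFGS)
#' optimization of the penalized multinomial log-likelihood with analytic
#' gradients.  `predict` returns expected relative abundances (rows on the
#' simplex); `sample` draws multinomial counts at supplied or training
#' sequencing depths (resampled with replacement when the requested row count
#' differs).
#'
#' @param prior_sigma2 prior variance of each coefficient (ridge scale).
#' @param tol convergence tolerance on the gradient max-norm.
#' @param maxit BFGS iteration cap per restart.
#' @return a [model_family()].
#' @export
family_lnm <- function(prior_sigma2 = 1, tol = 1e-6, maxit = 2000) {
  if (prior_sigma2 <= 0) abort("prior_sigma2 must be > 0", "medipath_value_error")
  model_family(
    name = "lnm",
    config = list(prior_sigma2 = prior_sigma2, tol = tol, maxit = maxit),
    fit = function(design, responses, config) {
      fit_lnm_map(design, responses, config)
    },
    predict = function(params, design) {
      Z <- cbind(1, design)
      phi_inverse(Z %*% t(params$B))
    },
    sample = function(params, design, depths = NULL, ...) {
      Z <- cbind(1, design)
      P <- phi_inverse(Z %*% t(params$B))
      n <- nrow(P)
      if (is.null(depths)) {
        depths <- if (n == length(params$depths)) {
          params$depths
        } else {
          sample(params$depths, n, replace = TRUE)
        }
      }
      t(vapply(seq_len(n),
               function(i) as.numeric(stats::rmultinom(1, depths[i], P[i, ])),
               numeric(ncol(P))))
    },
    residual_scale = function(params) params$sigma
  )
}

fit_lnm_map <- function(design, counts, config) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is_wholenumber(counts))) {
    abort("counts must be nonnegative integers", "medipath_value_error")
  }
  J <- ncol(counts)
  if (J < 2) abort("need at least 2 count categories", "medipath_value_error")
  depths <- rowSums(counts)
  if (any(depths <= 0)) {
    abort("every sample needs a positive total count", "medipath_value_error")
  }
  Z <- cbind(`(Intercept)` = 1, design)
  D <- ncol(Z)
  s2 <- config$prior_sigma2

  negloglik <- function(b) {
    B <- matrix(b, J - 1, D)
    eta <- cbind(Z %*% t(B), 0)
    m <- apply(eta, 1, max)
    lse <- m + log(rowSums(exp(eta - m)))
    -(sum(counts * (eta - lse)) - sum(b^2) / (2 * s2))
  }
  # analytic gradient of the negative penalized log-likelihood
  neggrad <- function(b) {
    B <- matrix(b, J - 1, D)
    eta <- cbind(Z %*% t(B), 0)
    m <- apply(eta, 1, max)
    ex <- exp(eta - m)
    P <- ex / rowSums(ex)
    resid <- counts - depths * P
    G <- -t(resid[, seq_len(J - 1), drop = FALSE]) %*% Z + matrix(b, J - 1, D) / s2
    as.numeric(G)
  }

  # Convergence: gradient max-norm relative to the count scale.  When the
  # prior dominates (tiny sigma^2, curvature ~ 1/sigma^2) the Newton step is
  # ~ sigma^2 * gradient, so the gradient is additionally damped by
  # min(1, sigma^2) to measure parameter-space convergence.
  depth_scale <- max(1, sum(depths) / nrow(counts))
  b <- numeric((J - 1) * D)
  for (attempt in 1:6) {
    opt <- stats::optim(b, negloglik, neggrad, method = "BFGS",
                        control = list(maxit = config$maxit, reltol = 1e-15))
    b <- opt$par
    gnorm <- max(abs(neggrad(b)))
    if (gnorm * min(1, s2) <= config$tol * depth_scale) break
  }
  if (gnorm * min(1, s2) > config$tol * depth_scale) {
    abort(sprintf("LNM optimizer did not converge (gradient max-norm %.3g)",
                  gnorm), "medipath_convergence_error")
  }
  B <- matrix(b, J - 1, D,
              dimnames = list(colnames(counts)[seq_len(J - 1)], colnames(Z)))
  P <- phi_inverse(Z %*% t(B))
  prop <- counts / depths
  sigma <- pmax(sqrt(colMeans((prop - P)^2)), .Machine$double.eps)
  list(B = B, depths = depths, sigma = sigma, grad_norm = gnorm)
}

#' Convenience wrapper fitting the logistic-normal multinomial family
#' @inheritParams fit_linear
#' @param counts nonnegative integer matrix n x J with positive row sums.
#' @param prior_sigma2 prior variance (ridge scale) for all coefficients.
#' @return a `fitted_family`.
#' @export
fit_lnm <- function(design, counts, prior_sigma2 = 1) {
  fit_family(family_lnm(prior_sigma2 = prior_sigma2), design, counts)
}

## ---- hurdle -----------------------------------------------------------------

#' Hurdle (two-part) model family for zero-inflated responses
#'
#' Per response: a logistic regression for presence (y > 0) and a linear
#' regression on log(y) over the positive part.  `predict` is the two-part
#' mean `P(present) * E[y | y > 0]`, with the conditional mean taken as the
#' lognormal mean `exp(mu + sigma^2 / 2)`.  `sample` draws presence, then a
#' lognormal magnitude.  Residual scales come from the positive part on the
#' log scale.  An all-zero response predicts identically zero (with a
#' warning); an all-positive response degrades to the positive part only.
#'
#' @return a [model_family()].
#' @export
family_hurdle <- function() {
  model_family(
    name = "hurdle",
    fit = function(design, responses, config) fit_hurdle_parts(design, responses),
    predict = function(params, design) {
      X <- cbind(1, design)
      R <- length(params$parts)
      out <- matrix(0, nrow(X), R)
      for (r in seq_len(R)) {
        p <- params$parts[[r]]
        if (p$all_zero) next
        pres <- if (is.null(p$zcoef)) 1 else stats::plogis(drop(X %*% p$zcoef))
        mu <- drop(X %*% p$pcoef)
        out[, r] <- pres * exp(mu + p$sigma^2 / 2)
      }
      out
    },
    sample = function(params, design, ...) {
      X <- cbind(1, design)
      R <- length(params$parts)
      out <- matrix(0, nrow(X), R)
      for (r in seq_len(R)) {
        p <- params$parts[[r]]
        if (p$all_zero) next
        pres <- if (is.null(p$zcoef)) {
          rep(1, nrow(X))
        } else {
          stats::rbinom(nrow(X), 1, stats::plogis(drop(X %*% p$zcoef)))
        }
        mu <- drop(X %*% p$pcoef)
        out[, r] <- pres * exp(stats::rnorm(nrow(X), mu, p$sigma))
      }
      out
    },
    residual_scale = function(params) {
      vapply(params$parts, function(p) p$sigma, numeric(1))
    }
  )
}

fit_hurdle_parts <- function(design, responses) {
  if (any(responses < 0)) {
    abort("hurdle responses must be nonnegative", "medipath_value_error")
  }
  X <- cbind(1, design)
  parts <- vector("list", ncol(responses))
  for (r in seq_len(ncol(responses))) {
    y <- responses[, r]
    pos <- y > 0
    if (!any(pos)) {
      warning(sprintf("response %d is all zeros; predicting 0", r), call. = FALSE)
      parts[[r]] <- list(all_zero = TRUE, sigma = .Machine$double.eps)
      next
    }
    zcoef <- NULL
    if (any(!pos)) {
      zfit <- suppressWarnings(
        stats::glm.fit(X, as.numeric(pos), family = stats::binomial())
      )
      zcoef <- ifelse(is.na(zfit$coefficients), 0, zfit$coefficients)
    }
    lfit <- ols_fit(X[pos, , drop = FALSE], cbind(log(y[pos])))
    parts[[r]] <- list(all_zero = FALSE, zcoef = zcoef,
                       pcoef = drop(lfit$coef),
                       sigma = max(lfit$sigma, .Machine$double.eps))
  }
  list(parts = parts)
}

#' Convenience wrapper fitting the hurdle family
#' @inheritParams fit_linear
#' @return a `fitted_family`.
#' @export
fit_hurdle <- function(design, responses) {
  fit_family(family_hurdle(), design, responses)
}

## ---- JSON sidecar serialization ---------------------------------------------

#' Serialize a fitted family to a JSON sidecar
#'
#' Stores the family name, configuration, coefficient arrays, and design
#' column names — enough for exact re-prediction after [read_fitted()].
#' Coefficient-based families (linear, regularized, LNM, hurdle) are
#' supported; random forests have no coefficient representation and must be
#' kept as R objects.
#'
#' @param object a `fitted_family`.
#' @param path output path for the JSON file.
#' @return `path`, invisibly.
#' @export
write_fitted <- function(object, path) {
  stopifnot(inherits(object, "fitted_family"))
  nm <- object$family$name
  if (nm == "random_forest") {
    abort("random forests have no JSON coefficient form; use saveRDS instead",
          "medipath_value_error")
  }
  payload <- list(family = nm, config = object$family$config,
                  response_names = object$response_names,
                  design_names = object$design_names,
                  params = object$params)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

#' Restore a fitted family from its JSON sidecar
#'
#' @param path a file written by [write_fitted()].
#' @return a `fitted_family` whose predictions reproduce the original's.
#' @export
read_fitted <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  family <- switch(p$family,
    linear = family_linear(),
    regularized_l1 = family_regularized("l1", lambda = p$config$lambda),
    regularized_l2 = family_regularized("l2", lambda = p$config$lambda),
    lnm = family_lnm(prior_sigma2 = p$config$prior_sigma2),
    hurdle = family_hurdle(),
    abort(sprintf("unknown serialized family '%s'", p$family),
          "medipath_value_error")
  )
  params <- p$params
  fix_mat <- function(m, rnames = NULL, cnames = NULL) {
    m <- as.matrix(m)
    if (!is.null(rnames)) rownames(m) <- rnames
    if (!is.null(cnames)) colnames(m) <- cnames
    m
  }
  if (p$family %in% c("linear", "regularized_l1", "regularized_l2")) {
    params$coef <- fix_mat(params$coef,
                           c("(Intercept)", p$design_names),
                           p$response_names)
    params$sigma <- as.numeric(params$sigma)
    if (!is.null(params$keep)) params$keep <- as.logical(params$keep)
  } else if (p$family == "lnm") {
    params$B <- fix_mat(params$B)
    params$depths <- as.numeric(params$depths)
    params$sigma <- as.numeric(params$sigma)
  } else if (p$family == "hurdle") {
    params$parts <- lapply(params$parts, function(pp) {
      list(all_zero = isTRUE(pp$all_zero),
           zcoef = if (!is.null(pp$zcoef)) as.numeric(pp$zcoef),
           pcoef = as.numeric(pp$pcoef),
           sigma = as.numeric(pp$sigma))
    })
  }
  structure(list(family = family, params = params,
                 response_names = p$response_names,
                 design_names = p$design_names),
            class = "fitted_family")
}
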