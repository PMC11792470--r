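# Independent oracles and tiny programmatic fixtures shared across tests.

# Noiseless linear chain: M = 2T + e, Y = 3M + 1T, with a deterministic,
# treatment-orthogonal perturbation e so the outcome design has full rank.
# Exactly interpolable: fitted coefficients are (2), (3, 1) to machine precision.
chain_exact <- function(n = 50) {
  stopifnot(n %% 4 == 0)   # even arms keep e exactly mean-zero per arm
  tr <- rep(c("control", "treated"), each = n / 2)
  tn <- as.numeric(tr == "treated")
  e <- rep_len(c(-0.5, 0.5), n)
  M1 <- 2 * tn + e
  df <- data.frame(treat = tr, M1 = M1, Y1 = 3 * M1 + tn)
  mediation_data(df, role_map("treat", "M1", "Y1"))
}

# Noisy linear chain with covariates, for closed-form coefficient identities.
chain_noisy <- function(n = 120, P = 1, seed = 42) {
  set.seed(seed)
  tr <- sample(c("control", "treated"), n, replace = TRUE)
  tn <- as.numeric(tr == "treated")
  X <- matrix(rnorm(n * P), n, P, dimnames = list(NULL, paste0("X", 1:P)))
  M1 <- 2 * tn + 0.5 * X[, 1] + rnorm(n)
  M2 <- -1 * tn + rnorm(n)
  Y1 <- 3 * M1 + 4 * M2 + 1 * tn + 0.3 * X[, 1] + rnorm(n)
  Y2 <- -2 * M1 + 0.5 * tn + rnorm(n)
  df <- data.frame(treat = tr, M1 = M1, M2 = M2, Y1 = Y1, Y2 = Y2, X)
  mediation_data(df, role_map("treat", c("M1", "M2"), c("Y1", "Y2"),
                              paste0("X", 1:P)))
}

# Coordinate-descent lasso for  sum_i (y_i - b0 - x_i'b)^2 + lambda * ||b||_1
# with an unpenalized intercept; independent of the glmnet-backed fit.
lasso_cd_oracle <- function(X, y, lambda, iters = 5000, tol = 1e-13) {
  p <- ncol(X)
  b <- rep(0, p)
  b0 <- mean(y)
  for (it in seq_len(iters)) {
    b_old <- b
    b0 <- mean(y - X %*% b)
    for (j in seq_len(p)) {
      r <- y - b0 - X[, -j, drop = FALSE] %*% b[-j]
      zj <- sum(X[, j] * r)
      b[j] <- sign(zj) * max(0, abs(zj) - lambda / 2) / sum(X[, j]^2)
    }
    if (max(abs(b - b_old)) < tol) break
  }
  c(b0, b)
}

# Penalized binomial logistic MAP:  maximize
#   sum_i log dbinom(y_i, N_i, plogis(b0 + x_i'b)) - sum(par^2) / (2 s2)
# (the J = 2 reduction of the logistic-normal multinomial objective),
# optimized directly over (b0, b) with a generic quasi-Newton routine.
logistic_map_oracle <- function(X, y1, N, s2) {
  Xi <- cbind(1, X)
  nll <- function(par) {
    eta <- drop(Xi %*% par)
    -(sum(stats::dbinom(y1, N, stats::plogis(eta), log = TRUE)) -
        sum(par^2) / (2 * s2))
  }
  stats::optim(rep(0, ncol(Xi)), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))$par
}

# Exhaustive-threshold FDR selection used to cross-check fdr_summary().
fdr_enumeration_oracle <- function(real, null, q) {
  cand <- sort(unique(c(abs(real), abs(null))))
  for (t in cand) {
    num <- sum(abs(null) > t)
    den <- num + sum(abs(real) > t)
    fdr <- if (den == 0) 0 else num / den
    if (fdr <= q) return(list(t_star = t, selected = abs(real) > t))
  }
  list(t_star = Inf, selected = rep(FALSE, length(real)))
}

# Minimal dense JSON BIOM document written as plain text.
write_biom_fixture <- function(path, n_samples = 4, n_taxa = 10, seed = 7) {
  set.seed(seed)
  counts <- matrix(rpois(n_taxa * n_samples, 20), n_taxa, n_samples)
  rows <- paste0(
    '{"id": "taxon', seq_len(n_taxa), '", "metadata": null}', collapse = ", ")
  cols <- paste0(
    '{"id": "sample', seq_len(n_samples), '", "metadata": null}', collapse = ", ")
  dat <- paste(apply(counts, 1, function(r) {
    paste0("[", paste(r, collapse = ","), "]")
  }), collapse = ", ")
  json <- sprintf(paste0(
    '{"id": "fixture", "format": "Biological Observation Matrix 1.0.0",',
    '"format_url": "http://biom-format.org",',
    '"type": "OTU table", "generated_by": "medipath-tests",',
    '"date": "2026-01-01T00:00:00",',
    '"matrix_type": "dense", "matrix_element_type": "int",',
    '"shape": [%d, %d], "rows": [%s], "columns": [%s], "data": [%s]}'),
    n_taxa, n_samples, rows, cols, dat)
  writeLines(json, path)
  counts
}
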