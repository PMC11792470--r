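test_that("linear family interpolates noiseless data exactly", {
  x <- matrix(seq_len(10), 10, 1, dimnames = list(NULL, "x"))
  y <- cbind(resp = 2 + 3 * x[, 1])
  fit <- fit_linear(x, y)
  expect_equal(unname(fit$params$coef[, 1]), c(2, 3), tolerance = 1e-12)
  expect_equal(unname(residual_scale(fit)), 0, tolerance = 1e-10)
  # constant response: zero slope, zero residual scale
  fit0 <- fit_linear(x, cbind(const = rep(5, 10)))
  expect_equal(unname(fit0$params$coef[, 1]), c(5, 0), tolerance = 1e-12)
  expect_equal(unname(residual_scale(fit0)), 0, tolerance = 1e-12)
})

test_that("rank-deficient designs warn and match the pseudoinverse oracle", {
  set.seed(1)
  x <- matrix(rnorm(20), 10, 2)
  x <- cbind(x, dup = x[, 1])
  colnames(x) <- c("a", "b", "dup")
  y <- cbind(rnorm(10))
  expect_warning(fit <- fit_linear(x, y), "rank-deficient")
  X1 <- cbind(1, x)
  oracle_fitted <- X1 %*% (MASS::ginv(X1) %*% y)
  expect_equal(unname(predict(fit, x)), unname(oracle_fitted), tolerance = 1e-8)
})

test_that("penalized family recovers OLS at lambda 0 and shrinks fully at large lambda", {
  set.seed(2)
  x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  y <- cbind(r1 = 1 + drop(x %*% c(2, -1)) + rnorm(100, sd = 0.3),
             r2 = -2 + drop(x %*% c(0.5, 1)) + rnorm(100, sd = 0.3))
  ols <- fit_linear(x, y)
  las <- fit_regularized(x, y, penalty = "l1", lambda = 0)
  expect_equal(unname(las$params$coef), unname(ols$params$coef),
               tolerance = 1e-4)
  big <- fit_regularized(x, y, penalty = "l1", lambda = 1e7)
  expect_equal(unname(big$params$coef[-1, ]), matrix(0, 2, 2))
  expect_equal(unname(predict(big, x)[1, ]), unname(colMeans(y)),
               tolerance = 1e-6)
  expect_error(family_regularized("l1", lambda = -1),
               class = "medipath_value_error")
})

test_that("lasso coefficients match an independent coordinate-descent oracle", {
  set.seed(3)
  x <- matrix(rnorm(120), 60, 2, dimnames = list(NULL, c("a", "b")))
  y <- cbind(r = 0.5 + drop(x %*% c(1.5, 0.2)) + rnorm(60, sd = 0.4))
  for (lam in c(5, 20, 80)) {
    fit <- fit_regularized(x, y, penalty = "l1", lambda = lam)
    oracle <- lasso_cd_oracle(x, y[, 1], lam)
    expect_equal(unname(fit$params$coef[, 1]), oracle, tolerance = 1e-4)
  }
})

test_that("auto lambda is selected by pooled CV and recorded", {
  set.seed(4)
  x <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- cbind(r1 = drop(x %*% c(2, 0, 0)) + rnorm(100, sd = 0.5),
             r2 = drop(x %*% c(0, 1.5, 0)) + rnorm(100, sd = 0.5))
  fit <- fit_regularized(x, y, penalty = "l1", lambda = "auto")
  expect_true(is.numeric(fit$params$lambda) && fit$params$lambda > 0)
  # signal coefficients survive CV-chosen shrinkage, noise stays small
  expect_gt(fit$params$coef["a", "r1"], 1)
  expect_lt(abs(fit$params$coef["c", "r1"]), 0.5)
})

test_that("random forests need a seed, are reproducible, and beat OLS on steps", {
  expect_error(family_random_forest(seed = NULL), class = "medipath_value_error")
  set.seed(5)
  x <- matrix(runif(400), 400, 1, dimnames = list(NULL, "x"))
  y <- cbind(step = ifelse(x[, 1] > 0.5, 3, 0) + rnorm(400, sd = 0.2))
  xt <- matrix(runif(200), 200, 1, dimnames = list(NULL, "x"))
  yt <- ifelse(xt[, 1] > 0.5, 3, 0)
  rf1 <- fit_random_forest(x, y, n_trees = 200, seed = 11)
  rf2 <- fit_random_forest(x, y, n_trees = 200, seed = 11)
  expect_identical(predict(rf1, xt), predict(rf2, xt))
  ols <- fit_linear(x, y)
  mse_rf <- mean((predict(rf1, xt) - yt)^2)
  mse_ols <- mean((predict(ols, xt) - yt)^2)
  expect_lt(mse_rf, mse_ols)
  expect_true(all(residual_scale(rf1) > 0))
})

test_that("phi_inverse maps to the simplex with saturation-safe arithmetic", {
  expect_equal(phi_inverse(c(0, 0, 0)), rep(1 / 4, 4))
  expect_equal(phi_inverse(log(2)), c(2 / 3, 1 / 3))
  big <- phi_inverse(c(1e4, 0, 0))
  expect_false(anyNA(big))
  expect_equal(sum(big), 1, tolerance = 1e-12)
  expect_gt(big[1], 1 - 1e-10)
  # matrix input maps row-wise
  P <- phi_inverse(matrix(c(0, log(2)), 2, 1))
  expect_equal(P[1, ], c(0.5, 0.5))
  expect_equal(P[2, ], c(2 / 3, 1 / 3))
})

test_that("LNM MAP with diffuse prior recovers pooled proportions", {
  set.seed(6)
  counts <- t(stats::rmultinom(40, 500, c(0.5, 0.3, 0.15, 0.05)))
  colnames(counts) <- paste0("t", 1:4)
  fit <- fit_lnm(matrix(numeric(0), 40, 0), counts, prior_sigma2 = 1e8)
  phat <- predict(fit, matrix(numeric(0), 40, 0))[1, ]
  pbar <- colSums(counts) / sum(counts)
  expect_equal(unname(phat), unname(pbar), tolerance = 1e-6)
})

test_that("LNM shrinks to the uniform composition as the prior tightens", {
  set.seed(7)
  counts <- t(stats::rmultinom(30, 200, c(0.7, 0.2, 0.1)))
  colnames(counts) <- paste0("t", 1:3)
  fit <- fit_lnm(matrix(numeric(0), 30, 0), counts, prior_sigma2 = 1e-8)
  expect_equal(unname(predict(fit, matrix(numeric(0), 30, 0))[1, ]),
               rep(1 / 3, 3), tolerance = 1e-4)
  expect_equal(unname(fit$params$B), matrix(0, 2, 1), tolerance = 1e-4)
})

test_that("binary LNM matches a penalized logistic oracle", {
  set.seed(8)
  x <- matrix(rnorm(50), 50, 1, dimnames = list(NULL, "x"))
  eta <- 0.5 + 1.2 * x[, 1]
  N <- rep(100, 50)
  y1 <- rbinom(50, N, plogis(eta))
  counts <- cbind(a = y1, b = N - y1)
  s2 <- 2
  fit <- fit_lnm(x, counts, prior_sigma2 = s2)
  oracle <- logistic_map_oracle(x, y1, N, s2)
  expect_equal(unname(as.numeric(fit$params$B)), unname(oracle),
               tolerance = 1e-5)
})

test_that("LNM validates counts and samples at requested depths", {
  x <- matrix(numeric(0), 5, 0)
  bad <- matrix(c(1.5, 2, 3, 4, 5, 6, 7, 8, 9, 10), 5, 2)
  expect_error(fit_lnm(x, bad), class = "medipath_value_error")
  set.seed(9)
  counts <- t(stats::rmultinom(5, 50, c(0.6, 0.4)))
  colnames(counts) <- c("a", "b")
  fit <- fit_lnm(x, counts)
  draw <- sample_family(fit, x, seed = 2, depths = rep(77, 5))
  expect_equal(unname(rowSums(draw)), rep(77, 5))
})

test_that("hurdle predictions equal the closed-form two-part mean", {
  set.seed(10)
  n <- 400
  pi0 <- 0.3      # zero probability
  cval <- 4
  y <- cbind(h = ifelse(runif(n) < pi0, 0, cval))
  x <- matrix(numeric(0), n, 0)
  fit <- fit_hurdle(x, y)
  obs_pi <- mean(y[, 1] == 0)
  expect_equal(unname(predict(fit, x)[1, 1]), (1 - obs_pi) * cval,
               tolerance = 1e-8)
  # all-positive column degrades to the positive part only
  ypos <- cbind(p = rep(cval, n))
  fitp <- fit_hurdle(x, ypos)
  expect_equal(unname(predict(fitp, x)[1, 1]), cval, tolerance = 1e-8)
  # all-zero column predicts identically zero with a warning
  expect_warning(fitz <- fit_hurdle(x, cbind(z = rep(0, n))), "all zeros")
  expect_equal(unname(predict(fitz, x)[, 1]), rep(0, n))
})

test_that("the family contract rejects objects missing a capability", {
  expect_error(
    model_family("broken", fit = function(d, r, c) list(),
                 predict = function(p, d) d, sample = NULL,
                 residual_scale = function(p) 1),
    class = "medipath_contract_error")
})

test_that("sample() means converge to predict() for additive-noise families", {
  set.seed(11)
  x <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "x"))
  y <- cbind(r = 1 + 2 * x[, 1] + rnorm(30, sd = 0.5))
  for (fit in list(fit_linear(x, y),
                   fit_regularized(x, y, penalty = "l2", lambda = 1),
                   fit_random_forest(x, y, n_trees = 50, seed = 3))) {
    mu <- predict(fit, x)
    draws <- lapply(1:400, function(s) sample_family(fit, x, seed = s))
    mbar <- Reduce(`+`, draws) / length(draws)
    sd_mc <- max(residual_scale(fit)) / sqrt(400)
    expect_lt(max(abs(mbar - mu)), 4 * max(sd_mc, 1e-3))
    # identical seeds give identical draws
    expect_identical(sample_family(fit, x, seed = 99),
                     sample_family(fit, x, seed = 99))
  }
})

test_that("JSON sidecars round-trip coefficient-based fits exactly", {
  set.seed(12)
  x <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  y <- cbind(r1 = 1 + drop(x %*% c(2, -1)) + rnorm(40, sd = 0.3),
             r2 = drop(x %*% c(0, 1)) + rnorm(40, sd = 0.3))
  yz <- cbind(h = ifelse(runif(40) < 0.3, 0,
                         exp(0.2 * x[, 1] + rnorm(40, sd = 0.2))))
  counts <- t(rmultinom(40, 150, c(0.5, 0.3, 0.2)))
  colnames(counts) <- paste0("t", 1:3)
  fits <- list(fit_linear(x, y),
               fit_regularized(x, y, "l1", lambda = 2),
               fit_lnm(x, counts, prior_sigma2 = 2),
               fit_hurdle(x, yz))
  for (fit in fits) {
    p <- tempfile(fileext = ".json")
    write_fitted(fit, p)
    back <- read_fitted(p)
    expect_lt(max(abs(predict(back, x) - predict(fit, x))), 1e-10)
    unlink(p)
  }
  rf <- fit_random_forest(x, y, n_trees = 3, seed = 1)
  expect_error(write_fitted(rf, tempfile()), class = "medipath_value_error")
})
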