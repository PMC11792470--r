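# single-pair linear chain fitted once per file; residual scales near 1
fit_sens_chain <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      set.seed(101)
      n <- 400
      tr <- rep(c("control", "treated"), n / 2)
      tn <- as.numeric(tr == "treated")
      M1 <- 2 * tn + rnorm(n)
      Y1 <- 3 * M1 + tn + rnorm(n)
      md <- mediation_data(data.frame(treat = tr, M1 = M1, Y1 = Y1),
                           role_map("treat", "M1", "Y1"))
      cache <<- list(data = md, model = estimate(multimedia(md), md))
    }
    cache
  }
})

test_that("Sigma(rho, G) assembles the documented block structure", {
  set.seed(50)
  tr <- rep(c("control", "treated"), 30)
  tn <- as.numeric(tr == "treated")
  M1 <- tn + rnorm(60, sd = 2)
  Y1 <- M1 + rnorm(60, sd = 3)
  md <- mediation_data(data.frame(treat = tr, M1 = M1, Y1 = Y1),
                       role_map("treat", "M1", "Y1"))
  m <- estimate(multimedia(md), md)
  sM <- unname(residual_scale(m$mediator_fit))
  sY <- unname(residual_scale(m$outcome_fit))
  S <- build_sigma_rho(m, 0.5, cbind(1, 1))
  expect_equal(S, rbind(c(sM^2, 0.5 * sM * sY), c(0.5 * sM * sY, sY^2)),
               tolerance = 1e-12)
  S0 <- build_sigma_rho(m, 0, cbind(1, 1))
  expect_equal(S0[1, 2], 0)
  expect_equal(S0[2, 1], 0)
})

test_that("Sigma with K = J = 1, sigma_M = 2, sigma_Y = 3, rho = 0.5 is [[4,3],[3,9]]", {
  # assemble through a model whose residual scales are forced to (2, 3)
  s <- fit_sens_chain()
  m <- s$model
  m$mediator_fit$params$sigma <- 2
  m$outcome_fit$params$sigma <- 3
  S <- build_sigma_rho(m, 0.5, cbind(1, 1))
  expect_equal(unname(S), rbind(c(4, 3), c(3, 9)), tolerance = 1e-12)
})

test_that("strong diffuse confounding patterns are rejected as non-PSD", {
  set.seed(51)
  n <- 90
  tr <- rep(c("control", "treated"), n / 2)
  tn <- as.numeric(tr == "treated")
  M <- sapply(1:3, function(k) tn + rnorm(n))
  colnames(M) <- paste0("M", 1:3)
  Y <- sapply(1:3, function(j) M %*% rep(0.5, 3) + rnorm(n))
  colnames(Y) <- paste0("Y", 1:3)
  md <- mediation_data(data.frame(treat = tr, M, Y),
                       role_map("treat", paste0("M", 1:3), paste0("Y", 1:3)))
  m <- estimate(multimedia(md), md)
  fullG <- expand.grid(1:3, 1:3)
  # eigenvalue oracle: the full-G coupling is rank-one per block and breaks
  # positive semidefiniteness well below |rho| = 1
  expect_error(build_sigma_rho(m, 0.999, fullG), class = "medipath_psd_error")
  S_ok <- build_sigma_rho(m, 0.2, fullG)
  expect_gte(min(eigen(S_ok, symmetric = TRUE)$values), -1e-10)
})

test_that("the rho = 0 anchor reproduces the unperturbed indirect estimate", {
  s <- fit_sens_chain()
  cfg <- sensitivity_config(rho_grid = c(-0.4, 0, 0.4), G = cbind(1, 1),
                            n_reps = 30, seed = 7)
  curve <- sensitivity(s$model, s$data, cfg)
  orig <- indirect_overall(s$model, s$data)$estimate
  at0 <- curve[curve$rho == 0, ]
  expect_lt(abs(at0$mean_effect - orig), 4 * at0$se)
  expect_false(at0$sign_flipped)
})

test_that("confounding drifts the refitted slope by rho * sigma_Y / sigma_M", {
  s <- fit_sens_chain()
  m <- s$model
  sM <- unname(residual_scale(m$mediator_fit))
  sY <- unname(residual_scale(m$outcome_fit))
  a_hat <- m$mediator_fit$params$coef["treattreated", 1]
  b_hat <- m$outcome_fit$params$coef["M1", 1]
  cfg <- sensitivity_config(rho_grid = c(-0.5, 0, 0.5), G = cbind(1, 1),
                            n_reps = 40, seed = 13)
  curve <- sensitivity(m, s$data, cfg)
  for (rho in c(-0.5, 0, 0.5)) {
    expected <- a_hat * (b_hat + rho * sY / sM)   # omitted-confounder bias
    row <- curve[curve$rho == rho, ]
    expect_lt(abs(row$mean_effect - expected), 4 * row$se + 1e-8)
  }
})

test_that("reported SE shrinks roughly as 1/sqrt(n_reps)", {
  s <- fit_sens_chain()
  se_at <- function(reps, seed) {
    cfg <- sensitivity_config(rho_grid = 0, G = cbind(1, 1),
                              n_reps = reps, seed = seed)
    mean(sensitivity(s$model, s$data, cfg)$se)
  }
  se_small <- mean(sapply(1:3, function(s2) se_at(8, s2)))
  se_big <- mean(sapply(1:3, function(s2) se_at(64, s2 + 10)))
  expect_lt(se_big, se_small)
  expect_equal(se_big / se_small, sqrt(8 / 64), tolerance = 0.5)
})

test_that("pathwise sensitivity tracks requested pairs and masked edges stay flat", {
  md <- chain_noisy(150)
  m <- estimate(multimedia(md), md)
  cfg <- sensitivity_config(rho_grid = c(-0.3, 0, 0.3),
                            G = cbind(c(1, 2), c(1, 1)), n_reps = 10, seed = 3)
  curve <- sensitivity_pathwise(m, md, cfg)
  expect_equal(length(unique(curve$effect)), 2)  # one trajectory per pair
  # pair behind a nullified T->M edge: indirect effect pinned at zero
  m0 <- estimate(nullify(multimedia(md), "T->M"), md)
  curve0 <- sensitivity_pathwise(m0, md, cfg)
  expect_equal(unique(curve0$mean_effect), 0)
})

test_that("perturbation sweeps match the rho parameterization on a single pair", {
  s <- fit_sens_chain()
  m <- s$model
  sM <- unname(residual_scale(m$mediator_fit))
  sY <- unname(residual_scale(m$outcome_fit))
  Delta <- rbind(c(0, sM * sY), c(sM * sY, 0))
  rho <- 0.4
  S_nu <- diag(c(sM^2, sY^2)) + rho * Delta
  expect_equal(unname(build_sigma_rho(m, rho, cbind(1, 1))), S_nu,
               tolerance = 1e-12)
  curve <- sensitivity_perturb(m, s$data, Delta, nu_grid = rho,
                               n_reps = 10, seed = 21)
  curve_rho <- sensitivity(m, s$data,
                           sensitivity_config(rho_grid = rho, G = cbind(1, 1),
                                              n_reps = 10, seed = 21))
  expect_equal(curve$mean_effect[curve$nu == rho],
               curve_rho$mean_effect[curve_rho$rho == rho], tolerance = 1e-10)
})

test_that("Delta = 0 leaves the curve at the unconfounded estimate", {
  s <- fit_sens_chain()
  curve <- sensitivity_perturb(s$model, s$data, matrix(0, 2, 2),
                               nu_grid = c(0, 1, 2), n_reps = 15, seed = 5)
  agg <- tapply(curve$mean_effect, curve$nu, mean)
  expect_lt(diff(range(agg)), 6 * max(curve$se))
  expect_error(
    sensitivity_perturb(s$model, s$data, matrix(c(0, 1, 0, 0), 2, 2),
                        nu_grid = 1, n_reps = 2, seed = 1),
    class = "medipath_value_error")
})

test_that("mediator-mediator noise correlation leaves linear indirect effects unbiased", {
  md <- chain_noisy(250)
  m <- estimate(multimedia(md), md)
  # Delta couples only the two mediators (entries 1-2 of the K+J = 4 block)
  Delta <- matrix(0, 4, 4)
  Delta[1, 2] <- Delta[2, 1] <- 0.5
  curve <- sensitivity_perturb(m, md, Delta, nu_grid = c(0, 1),
                               n_reps = 30, seed = 9)
  for (eff in unique(curve$effect)) {
    sub <- curve[curve$effect == eff, ]
    expect_lt(abs(diff(sub$mean_effect)), 4 * sqrt(sum(sub$se^2)))
  }
})

test_that("families without additive Gaussian residuals are refused", {
  fx <- make_toy_fixture("compositional", n = 40, seed = 2)
  m <- estimate(multimedia(fx$data, outcome_family = family_lnm(10)), fx$data)
  cfg <- sensitivity_config(rho_grid = 0.2, G = cbind(1, 1), n_reps = 2, seed = 1)
  expect_error(sensitivity(m, fx$data, cfg),
               class = "medipath_capability_error")
})
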