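test_that("hand-propagated chain effects: direct 1, indirect 6, total 7", {
  md <- chain_exact(40)
  m <- estimate(multimedia(md), md)
  expect_equal(direct_effect(m, md)$estimate, 1, tolerance = 1e-10)
  expect_equal(indirect_overall(m, md)$estimate, 6, tolerance = 1e-10)
  expect_equal(total_effect(m, md)$estimate, 7, tolerance = 1e-10)
  pw <- indirect_pathwise(m, md)
  expect_equal(pw$estimate, 6, tolerance = 1e-10)  # K = 1: pathwise == overall
})

test_that("effects are antisymmetric in the contrast", {
  md <- chain_noisy(80)
  m <- estimate(multimedia(md), md)
  for (fn in list(direct_effect, indirect_overall, indirect_pathwise)) {
    ab <- fn(m, md, c("treated", "control"))
    ba <- fn(m, md, c("control", "treated"))
    expect_equal(ab$estimate, -ba$estimate, tolerance = 1e-12)
  }
})

test_that("linear-family estimates equal products of fitted coefficients", {
  md <- chain_noisy(100)
  m <- estimate(multimedia(md), md)
  a_hat <- m$mediator_fit$params$coef["treattreated", ]     # T -> M_k
  b_hat <- m$outcome_fit$params$coef[c("M1", "M2"), ]       # M_k -> Y_j
  g_hat <- m$outcome_fit$params$coef["treattreated", ]      # T -> Y_j
  io <- indirect_overall(m, md)
  de <- direct_effect(m, md)
  expect_equal(unname(io$estimate), unname(colSums(a_hat * b_hat)),
               tolerance = 1e-10)
  expect_equal(unname(de$estimate), unname(g_hat), tolerance = 1e-10)
  pw <- indirect_pathwise(m, md)
  for (k in 1:2) {
    rows <- pw[pw$mediator == paste0("M", k), ]
    expect_equal(unname(rows$estimate), unname(a_hat[k] * b_hat[k, ]),
                 tolerance = 1e-10)
  }
})

test_that("total = direct + indirect and pathwise effects sum to the overall", {
  md <- chain_noisy(90)
  m <- estimate(multimedia(md), md)
  tot <- total_effect(m, md)$estimate
  de <- direct_effect(m, md)$estimate
  io <- indirect_overall(m, md)$estimate
  expect_equal(tot, de + io, tolerance = 1e-10)
  pw <- indirect_pathwise(m, md)
  pw_sum <- as.numeric(tapply(pw$estimate, pw$outcome, sum)[paste0("Y", 1:2)])
  expect_equal(pw_sum, unname(io), tolerance = 1e-10)
})

test_that("nullified edges force the corresponding effects to exactly zero", {
  md <- chain_noisy(70)
  base <- multimedia(md)
  m_tm <- estimate(nullify(base, "T->M"), md)
  expect_identical(unique(indirect_overall(m_tm, md)$estimate), 0)
  expect_identical(unique(indirect_pathwise(m_tm, md)$estimate), 0)
  m_ty <- estimate(nullify(base, "T->Y"), md)
  expect_identical(unique(direct_effect(m_ty, md)$estimate), 0)
  m_my <- estimate(nullify(base, "M->Y"), md)
  expect_identical(unique(indirect_overall(m_my, md)$estimate), 0)
  expect_identical(unique(indirect_pathwise(m_my, md)$estimate), 0)
})

test_that("two independent paths give product effects that add up", {
  fx <- make_toy_fixture("two_path", n = 4000, seed = 21)
  m <- estimate(multimedia(fx$data), fx$data)
  pw <- indirect_pathwise(m, fx$data)
  # truths: alpha (2, -1) x beta (3, 4) -> 6 and -4; overall 2
  expect_equal(pw$estimate[pw$mediator == "M1"], 6, tolerance = 0.4)
  expect_equal(pw$estimate[pw$mediator == "M2"], -4, tolerance = 0.4)
  expect_equal(indirect_overall(m, fx$data)$estimate, 2, tolerance = 0.5)
  expect_equal(sum(pw$estimate), indirect_overall(m, fx$data)$estimate,
               tolerance = 1e-10)
})

test_that("multilevel treatments report one row per named contrast", {
  set.seed(30)
  n <- 120
  tr <- sample(c("healthy", "cd", "uc"), n, replace = TRUE)
  dose <- ifelse(tr == "cd", 1, ifelse(tr == "uc", 0.5, 0))
  M1 <- 2 * dose + rnorm(n)
  Y1 <- 3 * M1 + dose + rnorm(n)
  md <- mediation_data(data.frame(treat = tr, M1 = M1, Y1 = Y1),
                       role_map("treat", "M1", "Y1"),
                       treatment_ref = c(treat = "healthy"))
  m <- estimate(multimedia(md), md)
  io <- indirect_overall(m, md)   # default: all levels vs reference
  expect_setequal(io$contrast, c("cd vs healthy", "uc vs healthy"))
  one <- indirect_overall(m, md, c("cd", "healthy"))
  expect_equal(one$estimate, io$estimate[io$contrast == "cd vs healthy"],
               tolerance = 1e-12)
  expect_equal(one$estimate, 6, tolerance = 1.2)
})

test_that("effect estimation runs unmodified across all five families", {
  set.seed(31)
  n <- 60
  tr <- rep(c("control", "treated"), n / 2)
  tn <- as.numeric(tr == "treated")
  M1 <- 1 + tn + rnorm(n, sd = 0.5)
  M2 <- 2 - 0.5 * tn + rnorm(n, sd = 0.5)
  Ypos <- round(exp(0.5 + 0.3 * M1 + rnorm(n, sd = 0.3)))
  Yz <- ifelse(runif(n) < 0.3, 0, Ypos + 1)
  Yc1 <- rpois(n, 50 + 10 * tn) + 1
  Yc2 <- rpois(n, 30) + 1
  df <- data.frame(treat = tr, M1 = M1, M2 = M2, Yz = Yz,
                   Yc1 = Yc1, Yc2 = Yc2)
  families <- list(
    linear = list(role_map("treat", c("M1", "M2"), "Yz"), family_linear()),
    lasso = list(role_map("treat", c("M1", "M2"), "Yz"),
                 family_regularized("l1", lambda = 1)),
    ridge = list(role_map("treat", c("M1", "M2"), "Yz"),
                 family_regularized("l2", lambda = 1)),
    forest = list(role_map("treat", c("M1", "M2"), "Yz"),
                  family_random_forest(n_trees = 30, seed = 4)),
    hurdle = list(role_map("treat", c("M1", "M2"), "Yz"), family_hurdle()),
    lnm = list(role_map("treat", c("M1", "M2"), c("Yc1", "Yc2")),
               family_lnm(prior_sigma2 = 10))
  )
  for (nm in names(families)) {
    md <- mediation_data(df[, c("treat", "M1", "M2",
                                if (nm == "lnm") c("Yc1", "Yc2") else "Yz")],
                         families[[nm]][[1]])
    m <- estimate(multimedia(md, outcome_family = families[[nm]][[2]]), md)
    for (fn in list(direct_effect, indirect_overall, indirect_pathwise)) {
      et <- fn(m, md)
      expect_true(all(is.finite(et$estimate)), info = nm)
    }
  }
})
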