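test_that("tree-prior kernels are proper densities on (0, t_root)", {
  expect_equal(bd_kernel_logpdf(50, 200), log(1 / 200))
  expect_equal(bd_kernel_logpdf(250, 200), -Inf)
  expect_equal(bd_kernel_logpdf(-1, 200), -Inf)
  bd <- tree_prior_params("birth-death", birth = 1, death = 0.5,
                          sampling = 0.1)
  for (troot in c(10, 150)) {
    total <- integrate(function(t) exp(bd_kernel_logpdf(t, troot, bd)),
                       0, troot, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  # critical case birth == death collapses to the uniform kernel
  crit <- tree_prior_params("birth-death", birth = 1, death = 1,
                            sampling = 1e-6)
  tt <- seq(5, 195, by = 5)
  expect_equal(bd_kernel_logpdf(tt, 200, crit), rep(log(1 / 200), length(tt)),
               tolerance = 1e-4)
})

test_that("joint prior reduces to the calibration density on two tips", {
  tr <- two_tip_tree()
  cal <- calibration("Root", "uniform", t_l = 10, t_u = 20)
  cs <- calibration_set(list(cal))
  for (t in c(12, 19.5, 30)) {
    expect_equal(log_joint_prior(t, tr, cs), log(dcal(t, cal)))
  }
  expect_equal(log_joint_prior(5, tr, cs), -Inf)  # below the hard minimum
})

test_that("order-violating states carry zero prior mass", {
  tr <- three_tip_tree()
  cs <- nested_cals()
  expect_equal(log_joint_prior(c(12, 14), tr, cs), -Inf)  # inner > root
  expect_true(is.finite(log_joint_prior(c(14, 12), tr, cs)))
})

test_that("constructions require an upper-bounded root calibration", {
  tr <- three_tip_tree()
  only_inner <- calibration_set(list(
    calibration("Inner", "uniform", t_l = 5, t_u = 15)))
  expect_error(log_joint_prior(c(14, 12), tr, only_inner), "root")
  cauchy_root <- calibration_set(list(
    calibration("Root", "cauchy", t_l = 10),
    calibration("Inner", "uniform", t_l = 5, t_u = 15)))
  expect_error(
    sample_prior(tr, cauchy_root, construction = "multiplicative",
                 mcmc = mcmc_settings(n_iter = 100, burn_in = 10)),
    "root")
})

test_that("infeasible calibration pairs fail loudly, naming the pair", {
  tr <- three_tip_tree()
  clash <- calibration_set(list(
    calibration("Root", "uniform", t_l = 8, t_u = 12, tail_r = 0),
    calibration("Inner", "uniform", t_l = 14, t_u = 18)))
  expect_error(
    sample_prior(tr, clash, mcmc = mcmc_settings(n_iter = 100, burn_in = 10)),
    "infeasible.*Inner.*Root")
})

test_that("truncation reshapes the inner marginal away from its
           specified density", {
  tr <- three_tip_tree()
  cs <- nested_cals()
  qd <- three_tip_quadrature(tr, cs)
  h <- qd$t[2] - qd$t[1]
  spec <- dcal(qd$t, cs[["Inner"]])
  tv <- 0.5 * sum(abs(qd$inner - spec / sum(spec * h) / h)) * h
  expect_gt(tv, 0.01)
})

test_that("single-calibration sampling reproduces the specified density", {
  tr <- two_tip_tree()
  cal <- calibration("Root", "uniform", t_l = 155.6, t_u = 251.4)
  s <- sample_prior(tr, calibration_set(list(cal)),
                    mcmc = mcmc_settings(n_iter = 1.4e5, burn_in = 2e4,
                                         thin = 1), seed = 1)
  x <- sort(s$draws[, 1L])
  n <- length(x)
  expect_gte(n, 1e5)
  ks <- max(abs(pcal(x, cal) - seq_len(n) / n))
  expect_lt(ks, 0.02)
  # effective 2.5% quantile matches the analytic quantile of the density
  expect_equal(unname(quantile(x, 0.025, type = 7)), qcal(0.025, cal),
               tolerance = 1)
})

test_that("chains are reproducible given the seed and always order-valid", {
  tr <- three_tip_tree()
  cs <- nested_cals()
  s1 <- sample_prior(tr, cs, mcmc = mcmc_settings(n_iter = 2e4,
                                                  burn_in = 5e3, thin = 5),
                     seed = 99)
  s2 <- sample_prior(tr, cs, mcmc = mcmc_settings(n_iter = 2e4,
                                                  burn_in = 5e3, thin = 5),
                     seed = 99)
  expect_identical(s1$draws, s2$draws)
  expect_true(all(s1$draws[, "Root"] > s1$draws[, "Inner"]))
  expect_true(all(s1$draws[, "Inner"] > 0))
})

test_that("sampled marginals match direct integration of the joint density", {
  tr <- three_tip_tree()
  cs <- nested_cals()
  for (constr in c("conditional", "multiplicative")) {
    qd <- three_tip_quadrature(tr, cs, construction = constr)
    s <- sample_prior(tr, cs, construction = constr,
                      mcmc = mcmc_settings(n_iter = 4.2e5, burn_in = 2e4,
                                           thin = 2), seed = 5)
    expect_lt(tv_draws_vs_grid(s$draws[, "Root"], qd$t, qd$root), 0.02)
    expect_lt(tv_draws_vs_grid(s$draws[, "Inner"], qd$t, qd$inner), 0.02)
  }
})

test_that("the two constructions yield measurably different marginals", {
  tr <- three_tip_tree()
  cs <- nested_cals()
  qc <- three_tip_quadrature(tr, cs, "conditional")
  qm <- three_tip_quadrature(tr, cs, "multiplicative")
  h <- qc$t[2] - qc$t[1]
  tv_root <- 0.5 * sum(abs(qc$root - qm$root)) * h
  expect_gt(tv_root, 0.01)
})

test_that("effective marginal summaries handle degenerate chains", {
  dummy <- structure(
    list(draws = matrix(7, nrow = 50, ncol = 1,
                        dimnames = list(NULL, "Root")),
         ess = c(Root = 50), seed = 1),
    class = "prior_samples")
  expect_warning(em <- effective_marginal(dummy, "Root"), "ESS")
  expect_equal(unname(em$quantiles), rep(7, 3))
  expect_equal(em$mean, 7)
  empty <- structure(list(draws = matrix(numeric(0), 0, 1,
                                         dimnames = list(NULL, "Root")),
                          ess = c(Root = 0), seed = 1),
                     class = "prior_samples")
  expect_error(effective_marginal(empty, "Root"), "empty")
})
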