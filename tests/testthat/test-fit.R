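test_that("Gibbs posterior matches a brute-force grid posterior on a tiny model", {
  # one construct, two items, no between level; every parameter except the
  # second loading fixed at truth.  The oracle integrates the factor out by
  # fine-grid quadrature and normalizes over a lambda grid.
  d <- tiny_onefactor_data(n_persons = 40L, lambda2 = 1.3, seed = 14)
  oracle <- tiny_posterior_grid(d$responses)

  tpl <- tiny_onefactor_template()
  pr <- prior_spec(beta_w_mean = 0, beta_b_mean = 0)
  st <- mcmc_settings(max_iterations = 20000, min_iterations = 20000,
                      check_interval = 20000, burn_in_fraction = 0.25,
                      seed = 14)
  fit <- fit_msem(d, tpl, pr, st)
  expect_equal(sum(fit$free), 1L)
  expect_equal(unname(fit$posterior_mean["lambda_w[2]"]), oracle$mean,
               tolerance = 0.04)
  expect_equal(unname(fit$posterior_sd["lambda_w[2]"]), oracle$sd,
               tolerance = 0.06)
})

test_that("posterior quantiles of prior-drawn truths are uniform", {
  # simulation consistency: lambda2 ~ N(1, 0.1) prior, simulate, fit, locate
  # the truth in its posterior; quantiles should be U(0, 1) across reps
  set.seed(100)
  n_rep <- 36
  lam_true <- rnorm(n_rep, 1, sqrt(0.1))
  q <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    d <- tiny_onefactor_data(n_persons = 40L, lambda2 = lam_true[r],
                             seed = 1000 + r)
    fit <- fit_msem(d, tiny_onefactor_template(),
                    prior_spec(beta_w_mean = 0, beta_b_mean = 0),
                    mcmc_settings(max_iterations = 2500,
                                  min_iterations = 2500,
                                  check_interval = 2500, seed = 1000 + r))
    draws <- fit$draws[[1]][, "lambda_w[2]"]
    q[r] <- mean(draws < lam_true[r])
  }
  expect_gt(stats::ks.test(q, "punif")$p.value, 0.01)
})

test_that("fits are deterministic given seed and settings", {
  cell <- grid_cell(items = 1, icc = 0.2)
  m <- make_population_model(cell)
  d <- simulate_dataset(m, cell, seed = 5)
  tpl <- template_for_condition(cell, m)
  pr <- priors_for_model(m)
  st <- quick_settings(5, max_iterations = 600, min_iterations = 600)
  f1 <- fit_msem(d, tpl, pr, st)
  f2 <- fit_msem(d, tpl, pr, st)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$posterior_mean, f2$posterior_mean)
})

test_that("constrained template with an empty set reproduces the free fit", {
  cell <- grid_cell(items = 0, icc = 0.2)
  m <- make_population_model(cell)
  d <- simulate_dataset(m, cell, seed = 6)
  pr <- priors_for_model(m)
  st <- quick_settings(6, max_iterations = 400, min_iterations = 400)
  free <- fit_msem(d, msem_template("free"), pr, st)
  con <- fit_msem(d, msem_template("constrained",
                                   constrained_items = integer(0)), pr, st)
  expect_identical(free$draws, con$draws)
})

test_that("cross-level equality holds draw for draw in constrained fits", {
  cell <- grid_cell(items = 2, icc = 0.2)
  m <- make_population_model(cell)
  d <- simulate_dataset(m, cell, seed = 7)
  tpl <- template_for_condition(cell, m)
  fit <- fit_msem(d, tpl, priors_for_model(m),
                  quick_settings(7, max_iterations = 400,
                                 min_iterations = 400))
  for (i in m$noniso_items)
    expect_identical(fit$draws[[1]][, sprintf("lambda_w[%d]", i)],
                     fit$draws[[1]][, sprintf("lambda_b[%d]", i)])
  # non-constrained items differ across levels
  expect_false(identical(fit$draws[[1]][, "lambda_w[2]"],
                         fit$draws[[1]][, "lambda_b[2]"]))
})

test_that("invalid data and template mismatches are rejected", {
  cell <- grid_cell()
  m <- make_population_model(cell)
  d <- simulate_dataset(m, cell, seed = 2)
  pr <- priors_for_model(m)
  bad <- d
  bad$responses[1, 1] <- 3L
  expect_error(fit_msem(bad, msem_template("free"), pr), "binary")
  ub <- d
  ub$cluster_id[1] <- 2L
  expect_error(fit_msem(ub, msem_template("free"), pr), "balanced")
  expect_error(fit_msem(d, tiny_onefactor_template(), pr), "expects 2 items")
  expect_error(msem_template("free", constrained_items = 2L), "free approach")
  expect_error(msem_template("constrained", constrained_items = 1L),
               "referent")
})

test_that("credible intervals bracket the posterior mean and admissibility holds", {
  cell <- grid_cell(items = 0, icc = 0.3)
  m <- make_population_model(cell)
  d <- simulate_dataset(m, cell, seed = 9)
  fit <- fit_msem(d, template_for_condition(cell, m), priors_for_model(m),
                  quick_settings(9, max_iterations = 800,
                                 min_iterations = 800))
  free <- fit$parameters[fit$free]
  ci <- fit$credible_interval_95[free, ]
  expect_true(all(ci[, "lower"] <= fit$posterior_mean[free]))
  expect_true(all(fit$posterior_mean[free] <= ci[, "upper"]))
  expect_true(fit$admissible)
})
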