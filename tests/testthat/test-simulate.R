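test_that("datasets are bit-identical given (model, cond, seed)", {
  cell <- grid_cell(items = 2, icc = 0.2)
  m <- make_population_model(cell)
  d1 <- simulate_dataset(m, cell, seed = 11, keep_latent = TRUE)
  d2 <- simulate_dataset(m, cell, seed = 11, keep_latent = TRUE)
  expect_identical(d1$responses, d2$responses)
  expect_identical(d1$latent, d2$latent)
  d3 <- simulate_dataset(m, cell, seed = 12)
  expect_false(identical(d1$responses, d3$responses))
  # balanced 0/1 matrix of the right size
  expect_equal(dim(d1$responses), c(600L, 12L))
  expect_true(all(d1$responses %in% c(0L, 1L)))
  expect_equal(unname(tabulate(d1$cluster_id)), rep(20L, 30L))
})

test_that("item marginals are symmetric around one half at zero thresholds", {
  cell <- list(structural_form = "homologous", noniso_position = "exogenous",
               icc = 0.2, n_noniso_items = 3, n_clusters = 600,
               cluster_size = 20)
  m <- make_population_model(cell)
  d <- simulate_dataset(m, cell, seed = 3)
  expect_true(all(abs(colMeans(d$responses) - 0.5) < 0.05))
})

test_that("latent second moments match the analytic covariance structure", {
  cell <- list(structural_form = "non_homologous", noniso_position = "exogenous",
               icc = 0.2, n_noniso_items = 3, n_clusters = 2500,
               cluster_size = 4)
  m <- make_population_model(cell, between_loading_delta = 1)
  d <- simulate_dataset(m, cell, seed = 9, keep_latent = TRUE)
  g <- m$item_construct
  phi_w <- matrix(c(1, m$beta_within, m$beta_within,
                    m$beta_within^2 + 1), 2)
  phi_b <- matrix(c(m$phi_b_exo, rep(m$beta_between * m$phi_b_exo, 2),
                    m$beta_between^2 * m$phi_b_exo + m$zeta_b_endo), 2)
  # same person: lw_i lw_k phiw + lb_i lb_k phib (+ theta + 1 on diagonal)
  S_theory <- outer(1:12, 1:12, function(i, k)
    m$lambda_within[i] * m$lambda_within[k] * phi_w[cbind(g[i], g[k])] +
    m$lambda_between[i] * m$lambda_between[k] * phi_b[cbind(g[i], g[k])])
  diag(S_theory) <- diag(S_theory) + m$theta_b + 1
  S_emp <- cov(d$latent)
  expect_lt(max(abs(S_emp - S_theory)), 0.12)
  # different person, same cluster: between part only
  a <- d$latent[seq(1, nrow(d$latent), by = 4), ]
  b <- d$latent[seq(2, nrow(d$latent), by = 4), ]
  C_emp <- cov(a, b)
  C_theory <- outer(1:12, 1:12, function(i, k)
    m$lambda_between[i] * m$lambda_between[k] * phi_b[cbind(g[i], g[k])])
  diag(C_theory) <- diag(C_theory) + m$theta_b
  expect_lt(max(abs(C_emp - C_theory)), 0.2)
  expect_lt(mean(abs(C_emp - C_theory)), 0.05)
})

test_that("cross-construct responses are independent when both paths are zero", {
  cell <- list(structural_form = "homologous", noniso_position = "exogenous",
               icc = 0.2, n_noniso_items = 0, n_clusters = 1500,
               cluster_size = 10)
  m <- make_population_model(cell)
  m$beta_within <- 1e-12   # exact zero is rejected by the positivity guard
  m$beta_between <- 1e-12
  m$zeta_b_endo <- m$phi_b_exo
  d <- simulate_dataset(m, cell, seed = 5, keep_latent = TRUE)
  cross <- cor(d$latent)[1:6, 7:12]
  expect_lt(max(abs(cross)), 0.03)
})

test_that("calibrated models reproduce their target ICC empirically", {
  for (target in c(0.10, 0.30)) {
    cell <- list(structural_form = "homologous", noniso_position = "exogenous",
                 icc = target, n_noniso_items = 0, n_clusters = 2000,
                 cluster_size = 20)
    m <- make_population_model(cell)
    d <- simulate_dataset(m, cell, seed = 21, keep_latent = TRUE)
    icc <- empirical_indicator_icc(d$latent, d$cluster_id)
    expect_true(all(abs(icc - target) < 0.025),
                label = paste("ICC near", target))
  }
})

test_that("indicator ICC increases strictly with between factor variance", {
  cell <- list(structural_form = "homologous", noniso_position = "exogenous",
               icc = 0.1, n_noniso_items = 0, n_clusters = 1200,
               cluster_size = 20)
  iccs <- sapply(c(0.05, 0.3, 0.8), function(phi) {
    m <- make_population_model(cell)
    m$phi_b_exo <- phi
    d <- simulate_dataset(m, cell, seed = 33, keep_latent = TRUE)
    mean(empirical_indicator_icc(d$latent[, 1:6], d$cluster_id))
  })
  expect_true(all(diff(iccs) > 0))
})

test_that("empirical ICC handles degenerate inputs as documented", {
  expect_error(empirical_indicator_icc(matrix(rnorm(20), 10), rep(1, 10)),
               "single cluster")
  # no between variance
  x <- matrix(rnorm(4000), 2000)
  expect_true(all(empirical_indicator_icc(x, rep(1:100, each = 20)) < 0.02))
  # constant within clusters, varying across
  y <- matrix(rep(rnorm(50), each = 10), ncol = 1)
  expect_equal(unname(empirical_indicator_icc(y, rep(1:50, each = 10))), 1)
})

test_that("dataset writer and reader round-trip through TSV + JSON sidecar", {
  cell <- grid_cell(items = 1)
  m <- make_population_model(cell)
  d <- simulate_dataset(m, cell, seed = 8, replication = 4L)
  path <- file.path(withr::local_tempdir(), "cell.tsv")
  write_msem_data(d, path)
  back <- read_msem_data(path)
  expect_identical(back$responses, d$responses)
  expect_equal(back$cluster_id, d$cluster_id)
  expect_equal(back$provenance$seed, 8)
  expect_equal(back$provenance$replication, 4)
})

test_that("non-positive variances are rejected before sampling", {
  cell <- grid_cell()
  m <- make_population_model(cell)
  m$phi_w_exo <- 0
  expect_error(simulate_dataset(m, cell, seed = 1), "strictly positive")
})
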