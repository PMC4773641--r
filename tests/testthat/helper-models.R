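# shared fixtures: small models and cheap fit settings, built in code

grid_cell <- function(approach = "constrained", form = "homologous",
                      pos = "exogenous", j = 30, icc = 0.10, items = 0,
                      global_seed = 1L) {
  g <- build_condition_grid(global_seed = global_seed)
  as.list(g[g$modeling_approach == approach & g$structural_form == form &
            g$noniso_position == pos & g$n_clusters == j & g$icc == icc &
            g$n_noniso_items == items, ])
}

quick_settings <- function(seed, max_iterations = 3000L,
                           min_iterations = 1000L, check_interval = 500L,
                           n_chains = 1L) {
  mcmc_settings(n_chains = n_chains, max_iterations = max_iterations,
                min_iterations = min_iterations,
                check_interval = check_interval, seed = seed)
}

# replicate simulate + fit over a cell; returns the cell summary
run_cell_reps <- function(cell, reps, delta = 0.5, seed_offset = 0L, ...) {
  model <- make_population_model(cell, between_loading_delta = delta)
  template <- template_for_condition(cell, model)
  priors <- priors_for_model(model)
  fits <- lapply(seq_len(reps), function(r) {
    seed <- cell$base_seed + seed_offset + r
    dat <- simulate_dataset(model, cell, seed = seed, replication = r)
    fit_msem(dat, template, priors, quick_settings(seed, ...))
  })
  summarize_cell(fits, model, cell)
}

# tiny single-construct measurement model without a between level, with every
# parameter except lambda[2] fixed at its generating value; used by the
# brute-force posterior oracle
tiny_onefactor_data <- function(n_persons = 40L, lambda2 = 1.3, seed = 1L) {
  model <- structure(list(
    lambda_within = c(1, lambda2), lambda_between = c(1, 1),
    item_construct = c(1L, 1L), referent_items = 1L, noniso_items = integer(0),
    phi_w_exo = 1, zeta_w_endo = 1, phi_b_exo = 0, zeta_b_endo = 0,
    theta_b = c(0, 0), tau = c(0, 0), beta_within = 0, beta_between = 0,
    between_loading_delta = 0, icc = 0), class = "msem_population")
  # 8 clusters only to satisfy the balanced-cluster contract; no between part
  cond <- list(n_clusters = 8L, cluster_size = n_persons / 8L)
  simulate_dataset(model, cond, seed = seed)
}

tiny_onefactor_template <- function(fix_lambda2 = NULL) {
  fixed <- list(tau = c("1" = 0, "2" = 0), phi_w_exo = 1)
  if (!is.null(fix_lambda2)) fixed$lambda_w <- c("2" = fix_lambda2)
  msem_template("free", item_construct = c(1L, 1L), referent_items = 1L,
                between = FALSE, fixed = fixed)
}

# independent brute-force posterior for lambda_w[2] in the tiny model:
# per-person likelihood integrates the single factor over a Gauss-Hermite-like
# fine grid; posterior over a fine lambda grid with the N(1, 0.1) prior
tiny_posterior_grid <- function(y, lambda_grid = seq(-0.5, 3.5, by = 0.01),
                                eta_grid = seq(-6, 6, by = 0.02)) {
  w_eta <- dnorm(eta_grid) * 0.02
  # aggregate the four response patterns (y1, y2)
  counts <- table(factor(y[, 1], 0:1), factor(y[, 2], 0:1))
  p1 <- pnorm(eta_grid)            # P(y1 = 1 | eta); loading fixed at 1
  loglik <- vapply(lambda_grid, function(l) {
    p2 <- pnorm(l * eta_grid)      # P(y2 = 1 | eta)
    ll <- 0
    for (a in 0:1) for (b in 0:1) {
      n_ab <- counts[a + 1, b + 1]
      if (n_ab == 0) next
      lik <- sum((if (a == 1) p1 else 1 - p1) *
                 (if (b == 1) p2 else 1 - p2) * w_eta)
      ll <- ll + n_ab * log(lik)
    }
    ll
  }, numeric(1))
  logpost <- loglik + dnorm(lambda_grid, 1, sqrt(0.1), log = TRUE)
  post <- exp(logpost - max(logpost))
  post <- post / sum(post)
  list(mean = sum(lambda_grid * post),
       sd = sqrt(sum(lambda_grid^2 * post) - sum(lambda_grid * post)^2))
}
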