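fast_cfg <- function(...) {
  as_run_config(utils::modifyList(list(
    grid = list(modeling_approach = "constrained",
                structural_form = "homologous",
                noniso_position = "exogenous",
                n_clusters = 30L, icc = 0.30, n_noniso_items = 1L),
    replications = 2L,
    mcmc = list(max_iterations = 2500L, min_iterations = 500L,
                check_interval = 500L, psr_threshold = 1.15)), list(...)))
}

test_that("a one-cell smoke run produces a manifest and a summary", {
  out <- run_experiment(fast_cfg())
  expect_length(out$summaries, 1L)
  s <- out$summaries[[1]]
  expect_s3_class(s, "msem_cell_summary")
  expect_equal(s$n_reps, 2L)
  expect_equal(out$manifest$status, "done")
  expect_equal(out$manifest$n_cells, 1L)
})

test_that("identical configurations reproduce identical summaries", {
  a <- run_experiment(fast_cfg())
  b <- run_experiment(fast_cfg())
  expect_identical(a$summaries[[1]]$replication_means,
                   b$summaries[[1]]$replication_means)
  expect_identical(a$summaries[[1]]$beta_rel_bias,
                   b$summaries[[1]]$beta_rel_bias)
})

test_that("incremental outputs are written and reused on re-run", {
  dir <- withr::local_tempdir()
  cfg <- fast_cfg(output_dir = dir)
  out1 <- run_experiment(cfg)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_length(list.files(dir, pattern = "^cell"), 1L)
  out2 <- run_experiment(cfg)
  expect_equal(out2$manifest$status, "cached")
})

test_that("invalid configurations fail before any computation", {
  expect_error(as_run_config(list(replicas = 10)), "unknown configuration")
  expect_error(as_run_config(list(mcmc = list(chains = 3))), "unknown mcmc")
  expect_error(run_experiment(list(grid = list(icc = 0.15))),
               "unregistered level")
})

test_that("YAML configurations round-trip through the reader", {
  path <- file.path(withr::local_tempdir(), "run.yaml")
  writeLines(c("grid:",
               "  modeling_approach: constrained",
               "  icc: [0.10, 0.20]",
               "replications: 5",
               "global_seed: 7",
               "mcmc:",
               "  max_iterations: 1000"), path)
  cfg <- read_run_config(path)
  expect_s3_class(cfg, "msem_config")
  expect_equal(cfg$replications, 5L)
  expect_equal(cfg$grid$icc, c(0.10, 0.20))
  expect_equal(cfg$mcmc$max_iterations, 1000L)
})

# fabricated summaries spanning a full table block
fake_summary <- function(j, icc, items, approach = "constrained",
                         form = "homologous", pos = "exogenous") {
  structure(list(
    cell = list(modeling_approach = approach, structural_form = form,
                noniso_position = pos, n_clusters = j, icc = icc,
                n_noniso_items = items),
    n_reps = 10L, n_used = 10L, convergence_rate = 1, admissibility_rate = 1,
    mean_ppp = 0.5, prop_ppp_above_half = 0.5,
    loading_sum_bias = c(within_exo = -0.1, within_endo = -0.1,
                         between_exo = 0.2, between_endo = 0.05),
    variance_rel_bias = c(within_exo_var = -5, within_endo_resid = 2,
                          between_exo_var = 10, between_endo_resid = 3),
    variance_coverage = c(within_exo_var = 0.9, within_endo_resid = 0.92,
                          between_exo_var = 0.88, between_endo_resid = 0.91),
    beta_rel_bias = c(beta_within = 12.4, beta_between = -9.6),
    beta_coverage = c(beta_within = 0.91, beta_between = 0.93)),
    class = "msem_cell_summary")
}

test_that("rendered tables have the study layout, order and rounding", {
  expect_identical(render_tables(list()), list())

  sums <- list()
  for (j in c(30, 50, 100)) for (icc in c(0.10, 0.20, 0.30))
    for (it in 0:3) sums <- c(sums, list(fake_summary(j, icc, it)))
  tabs <- render_tables(sums, kind = "structural")
  expect_length(tabs, 1L)
  tab <- tabs[[1]]
  expect_equal(nrow(tab), 36L)  # 3 j x 3 ICC x 4 item levels
  expect_equal(names(tab)[1:3], c("j", "icc", "items"))
  expect_equal(tab$within_beta_rel_bias[1], 12)      # integer rounding
  expect_equal(tab$within_beta_coverage[1], 0.91)    # 2 dp
  expect_true(!is.unsorted(tab$j))

  m <- render_tables(sums, kind = "measurement")[[1]]
  expect_equal(nrow(m), 36L)
  expect_equal(m$w_exo_load_sum_bias[1], -0.1)
  expect_equal(m$b_exo_var_rel_bias[1], 10)

  # single-cell input -> one data row
  one <- render_tables(list(fake_summary(30, 0.2, 1)))[[1]]
  expect_equal(nrow(one), 1L)
})

test_that("low-ICC cells are excluded from comparisons unless requested", {
  sums <- list(fake_summary(30, 0.05, 1), fake_summary(30, 0.20, 1))
  expect_equal(nrow(render_tables(sums)[[1]]), 1L)
  expect_equal(nrow(render_tables(sums, include_low_icc = TRUE)[[1]]), 2L)
})

test_that("groups with different designs render as separate tables", {
  sums <- list(fake_summary(30, 0.2, 1),
               fake_summary(30, 0.2, 1, pos = "endogenous"))
  tabs <- render_tables(sums)
  expect_length(tabs, 2L)
})

test_that("grid export writes one row per cell with seeds", {
  path <- file.path(withr::local_tempdir(), "grid.tsv")
  g <- build_condition_grid(list(icc = 0.05))
  write_grid(g, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), nrow(g))
  expect_true(all(c("cell_index", "base_seed") %in% names(back)))
})
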