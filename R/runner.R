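#' Read a run configuration
#'
#' YAML file naming grid restrictions, replications, MCMC settings, PPP
#' options and the global seed.  Missing entries fall back to package
#' defaults.
#'
#' @param path YAML file.
#' @return configuration list (class \code{"msem_config"}).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @param config a plain list with the same structure.
#' @rdname read_run_config
#' @export
as_run_config <- function(config) {
  defaults <- list(grid = NULL, replications = 100L, cluster_size = 20L,
                   global_seed = 1L, between_loading_delta = 0.5,
                   mcmc = list(), ppp = FALSE, ppp_draws = 100L,
                   output_dir = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration entries: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  bad_mcmc <- setdiff(names(cfg$mcmc),
                      names(formals(mcmc_settings)))
  if (length(bad_mcmc))
    stop("unknown mcmc settings: ", paste(bad_mcmc, collapse = ", "))
  structure(cfg, class = "msem_config")
}

#' Run a (subset of the) Monte Carlo experiment end to end
#'
#' For every selected cell: simulate \code{replications} datasets from the
#' cell's population model, fit the cell's modeling approach to each, and
#' aggregate with \code{\link{summarize_cell}}.  Per-replication seeds are
#' \code{base_seed + r}, so results are independent of scheduling order, and
#' per-cell summaries are written incrementally (and skipped on re-run) when
#' \code{output_dir} is set.  Replication failures are caught, logged and
#' counted; they never abort the sweep.
#'
#' @param config \code{msem_config}, plain list, or YAML path.
#' @param verbose print per-cell progress.
#' @return list with \code{summaries} (per cell) and \code{manifest}.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!inherits(config, "msem_config")) config <- as_run_config(config)
  grid <- build_condition_grid(config$grid,
                               cluster_size = config$cluster_size,
                               replications = config$replications,
                               global_seed = config$global_seed)
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  summaries <- vector("list", nrow(grid))
  status <- character(nrow(grid))
  t0 <- Sys.time()
  for (ci in seq_len(nrow(grid))) {
    cell <- grid[ci, ]
    tag <- sprintf("cell%03d", cell$cell_index)
    cache <- if (!is.null(out_dir)) file.path(out_dir, paste0(tag, ".rds.tsv"))
    if (!is.null(out_dir) && file.exists(cache)) {
      status[ci] <- "cached"
      summaries[[ci]] <- NULL
      next
    }
    res <- tryCatch(
      run_cell(cell, config),
      error = function(e) e)
    if (inherits(res, "error")) {
      status[ci] <- paste("failed:", conditionMessage(res))
      next
    }
    summaries[[ci]] <- res
    status[ci] <- "done"
    if (!is.null(out_dir)) {
      row <- cbind(as.data.frame(cell), .summary_row(res))
      utils::write.table(row, cache, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    if (verbose)
      message(tag, ": ", status[ci], " (",
              round(difftime(Sys.time(), t0, units = "secs")), "s elapsed)")
  }
  manifest <- list(
    config = unclass(config),
    n_cells = nrow(grid),
    cell_index = grid$cell_index,
    status = status,
    package_version = as.character(utils::packageVersion("msemiso")),
    started = format(t0), finished = format(Sys.time())
  )
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  list(summaries = summaries[!vapply(summaries, is.null, logical(1))],
       manifest = manifest)
}

#' Simulate, fit and summarize one cell
#'
#' @param cell one grid row.
#' @param config run configuration (see \code{\link{as_run_config}}).
#' @return \code{msem_cell_summary}.
#' @export
run_cell <- function(cell, config = as_run_config(list())) {
  if (!inherits(config, "msem_config")) config <- as_run_config(config)
  cell <- as.list(cell)
  model <- make_population_model(cell,
             between_loading_delta = config$between_loading_delta)
  template <- template_for_condition(cell, model)
  priors <- priors_for_model(model)
  reps <- cell$replications %||% config$replications
  fits <- vector("list", reps)
  for (r in seq_len(reps)) {
    seed <- cell$base_seed + r
    dat <- simulate_dataset(model, cell, seed = seed, replication = r)
    settings <- do.call(mcmc_settings,
                        utils::modifyList(config$mcmc, list(seed = seed)))
    fit <- fit_msem(dat, template, priors, settings)
    if (isTRUE(config$ppp) || (is.numeric(config$ppp) && config$ppp > 0))
      fit$ppp <- compute_ppp(fit, dat, n_draws = config$ppp_draws, seed = seed)
    fits[[r]] <- fit
  }
  summarize_cell(fits, model, cell)
}

# flat one-row data.frame of a cell summary (for incremental output)
.summary_row <- function(s) {
  data.frame(
    n_reps = s$n_reps, n_used = s$n_used,
    convergence_rate = s$convergence_rate,
    admissibility_rate = s$admissibility_rate,
    mean_ppp = s$mean_ppp, prop_ppp_above_half = s$prop_ppp_above_half,
    t(s$loading_sum_bias), t(s$variance_rel_bias), t(s$variance_coverage),
    t(s$beta_rel_bias), t(s$beta_coverage),
    check.names = FALSE
  )
}

#' Render per-cell summaries as study-style tables
#'
#' Groups summaries by (modeling approach, structural form, non-isomorphism
#' position) and renders one table per group: measurement tables list, per
#' construct and level, the loading-sum bias (2 dp), variance relative bias
#' (integer %) and variance coverage (2 dp); structural tables list relative
#' bias (integer %) and coverage (2 dp) of the within and between paths.
#' Cells with ICC 0.05 are excluded by default because structural estimation
#' is inaccurate there even for correctly specified models.
#'
#' @param summaries list of \code{msem_cell_summary}.
#' @param kind \code{"measurement"} or \code{"structural"}.
#' @param include_low_icc include ICC 0.05 cells.
#' @return named list of data.frames, one per group, rows ordered by
#'   (j, ICC, items).
#' @export
render_tables <- function(summaries, kind = c("structural", "measurement"),
                          include_low_icc = FALSE) {
  kind <- match.arg(kind)
  if (!length(summaries))
    return(list())
  cells <- lapply(summaries, `[[`, "cell")
  keep <- vapply(cells, function(cl)
    include_low_icc || cl$icc > 0.05, logical(1))
  summaries <- summaries[keep]
  if (!length(summaries)) return(list())
  key <- vapply(summaries, function(s)
    paste(s$cell$modeling_approach, s$cell$structural_form,
          s$cell$noniso_position, sep = "."), character(1))
  groups <- split(summaries, key)
  lapply(groups, function(grp) {
    rows <- lapply(grp, function(s) {
      base <- data.frame(j = s$cell$n_clusters, icc = s$cell$icc,
                         items = s$cell$n_noniso_items)
      if (kind == "structural")
        cbind(base, data.frame(
          within_beta_rel_bias = round(s$beta_rel_bias[["beta_within"]]),
          within_beta_coverage = round(s$beta_coverage[["beta_within"]], 2),
          between_beta_rel_bias = round(s$beta_rel_bias[["beta_between"]]),
          between_beta_coverage = round(s$beta_coverage[["beta_between"]], 2)))
      else
        cbind(base, data.frame(
          w_exo_load_sum_bias = round(s$loading_sum_bias[["within_exo"]], 2),
          w_exo_var_rel_bias = round(s$variance_rel_bias[["within_exo_var"]]),
          w_exo_var_cov = round(s$variance_coverage[["within_exo_var"]], 2),
          w_endo_load_sum_bias = round(s$loading_sum_bias[["within_endo"]], 2),
          w_endo_var_rel_bias = round(s$variance_rel_bias[["within_endo_resid"]]),
          w_endo_var_cov = round(s$variance_coverage[["within_endo_resid"]], 2),
          b_exo_load_sum_bias = round(s$loading_sum_bias[["between_exo"]], 2),
          b_exo_var_rel_bias = round(s$variance_rel_bias[["between_exo_var"]]),
          b_exo_var_cov = round(s$variance_coverage[["between_exo_var"]], 2),
          b_endo_load_sum_bias = round(s$loading_sum_bias[["between_endo"]], 2),
          b_endo_var_rel_bias = round(s$variance_rel_bias[["between_endo_resid"]]),
          b_endo_var_cov = round(s$variance_coverage[["between_endo_resid"]], 2)))
    })
    tab <- do.call(rbind, rows)
    tab <- tab[order(tab$j, tab$icc, tab$items), , drop = FALSE]
    rownames(tab) <- NULL
    tab
  })
}

#' Write rendered tables as tab-delimited files
#'
#' @param tables result of \code{render_tables}.
#' @param dir output directory.
#' @return written paths, invisibly.
#' @export
write_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0("table_", nm, ".tsv"))
    utils::write.table(tables[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
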