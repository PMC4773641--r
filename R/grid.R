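#' @useDynLib msemiso, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif qnorm pnorm quantile sd var ks.test rgamma setNames
NULL

# Registered factor levels of the experimental design.  Every grid request is
# validated against these; adding a level means editing this table.
.grid_levels <- list(
  modeling_approach = c("free", "constrained"),
  structural_form   = c("homologous", "non_homologous"),
  noniso_position   = c("exogenous", "endogenous"),
  n_clusters        = c(30L, 50L, 100L),
  icc               = c(0.05, 0.10, 0.20, 0.30),
  n_noniso_items    = 0:3
)

#' Build the experimental condition grid
#'
#' Enumerates the full crossed design of the simulation study: 2 modeling
#' approaches x 2 structural forms x 2 positions of the non-isomorphic
#' measurement model x 3 level-2 sample sizes x 4 indicator ICC levels x
#' 4 degrees of non-isomorphism = 384 cells.  Cells are ordered
#' lexicographically over the factors in the order
#' (modeling_approach, structural_form, noniso_position, n_clusters, icc,
#' n_noniso_items), with the last factor varying fastest, so cell indices are
#' stable across runs.  Each cell carries a reproducible
#' \code{base_seed = global_seed + cell_index}; replication \code{r} of a cell
#' uses \code{base_seed + r}.
#'
#' @param overrides named list restricting factors to subsets of their
#'   registered levels, e.g. \code{list(icc = c(0.10, 0.20))}.  Unknown factor
#'   names or unregistered levels are an error.
#' @param cluster_size level-1 units per cluster (balanced); default 20.
#' @param replications replications per cell carried on each row (default 100).
#' @param global_seed integer from which per-cell seeds are derived.
#' @return data.frame with one row per condition (class
#'   \code{"msem_condition_grid"}), columns \code{cell_index},
#'   the six design factors, \code{cluster_size}, \code{replications},
#'   \code{base_seed}.
#' @examples
#' nrow(build_condition_grid())                      # 384
#' nrow(build_condition_grid(list(modeling_approach = "constrained")))  # 192
#' @export
build_condition_grid <- function(overrides = NULL, cluster_size = 20L,
                                 replications = 100L, global_seed = 1L) {
  levels <- .grid_levels
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("overrides must be a named list of factor levels")
    for (nm in names(overrides)) {
      if (!nm %in% names(levels))
        stop("unknown design factor: '", nm, "'")
      bad <- setdiff(overrides[[nm]], levels[[nm]])
      if (length(bad))
        stop("unregistered level(s) for factor '", nm, "': ",
             paste(bad, collapse = ", "))
    }
  }
  # full grid first so that cell_index is invariant under restriction
  full <- expand.grid(
    n_noniso_items    = levels$n_noniso_items,
    icc               = levels$icc,
    n_clusters        = levels$n_clusters,
    noniso_position   = levels$noniso_position,
    structural_form   = levels$structural_form,
    modeling_approach = levels$modeling_approach,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  full <- full[, rev(names(full))]
  full$cell_index <- seq_len(nrow(full))
  keep <- rep(TRUE, nrow(full))
  if (!is.null(overrides))
    for (nm in names(overrides))
      keep <- keep & full[[nm]] %in% overrides[[nm]]
  grid <- full[keep, , drop = FALSE]
  grid$cluster_size <- as.integer(cluster_size)
  grid$replications <- as.integer(replications)
  grid$base_seed <- as.integer(global_seed) + grid$cell_index
  grid <- grid[, c("cell_index", "modeling_approach", "structural_form",
                   "noniso_position", "n_clusters", "icc", "n_noniso_items",
                   "cluster_size", "replications", "base_seed")]
  rownames(grid) <- NULL
  class(grid) <- c("msem_condition_grid", "data.frame")
  grid
}

# factor:residual split of the between variance, anchored so the between
# exogenous factor variance equals 0.44 in the ICC = 0.30 condition
# (within total variance 2): share = 0.44 / (2 * 0.30 / 0.70).
.between_factor_share <- function() 0.44 / (2 * 0.30 / 0.70)

#' Calibrate between-level variances to a target indicator ICC
#'
#' For a latent-response (probit) indicator with unit loadings, the within
#' total variance is the within factor variance plus the unit probit residual.
#' The total between variance \eqn{t} solves \eqn{t / (t + w) = ICC} exactly,
#' where \eqn{w} is the within total variance, and is split between the factor
#' variance and the indicator residual variance according to
#' \code{factor_share}.  The default share is anchored so the between
#' exogenous factor variance equals 0.44 at ICC 0.30 (with \eqn{w = 2}), and
#' is held constant across ICC levels.
#'
#' @param target_icc proportion in [0, 1); the observed-indicator ICC.
#' @param within_total_variance within-level total latent-response variance
#'   (factor + probit residual); 2 for a unit-loading exogenous indicator.
#' @param factor_share fraction of the between variance assigned to the
#'   factor; remainder goes to the indicator residual.
#' @return list with \code{factor_variance}, \code{indicator_residual_variance}
#'   and their sum \code{total_between}.
#' @examples
#' calibrate_between_variances(0.30)  # total between 6/7 = 0.857...
#' @export
calibrate_between_variances <- function(target_icc,
                                        within_total_variance = 2,
                                        factor_share = .between_factor_share()) {
  if (!is.numeric(target_icc) || length(target_icc) != 1L ||
      is.na(target_icc) || target_icc < 0 || target_icc >= 1)
    stop("target_icc must be a single value in [0, 1)")
  if (within_total_variance <= 0)
    stop("within_total_variance must be positive")
  if (factor_share < 0 || factor_share > 1)
    stop("factor_share must lie in [0, 1]")
  t <- within_total_variance * target_icc / (1 - target_icc)
  list(factor_variance = factor_share * t,
       indicator_residual_variance = (1 - factor_share) * t,
       total_between = t)
}

#' Construct the population generating model for a design cell
#'
#' Translates one condition of the grid into the full parameter set of the
#' two-level probit SEM: within/between loadings per construct (referent item
#' fixed at 1 on both levels), structural paths, and between-level variances
#' calibrated so that isomorphic indicators of both constructs hit the cell's
#' target ICC exactly.
#'
#' Items 1-6 measure the exogenous construct, items 7-12 the endogenous one;
#' the referent items are 1 and 7.  The \code{n_noniso_items} highest-numbered
#' non-referent items of the construct at \code{noniso_position} receive a
#' between loading of \code{1 + between_loading_delta}; all other items are
#' isomorphic with loadings 1 at both levels.  Homologous cells use structural
#' paths (0.44, 0.44); non-homologous cells use (0.31, 0.44).
#'
#' The endogenous between residual variance is set so the endogenous
#' indicators hit the same target ICC given the between path:
#' \code{zeta_b_endo = share * t_endo - beta_b^2 * phi_b_exo}, where
#' \code{t_endo} is the total between variance solving the ICC equation for
#' the endogenous within total variance \code{2 + beta_w^2}.
#'
#' @param cond single-row condition (one row of \code{build_condition_grid()}
#'   or a list with the same fields).
#' @param between_loading_delta increment of the between loading for
#'   non-isomorphic items (their between loading is \code{1 + delta}).
#' @return object of class \code{"msem_population"}: a list with fields
#'   \code{lambda_within}, \code{lambda_between} (length 12),
#'   \code{item_construct}, \code{referent_items}, \code{noniso_items},
#'   \code{phi_w_exo}, \code{zeta_w_endo}, \code{phi_b_exo},
#'   \code{zeta_b_endo}, \code{theta_b} (length 12), \code{tau} (length 12),
#'   \code{beta_within}, \code{beta_between}.
#' @export
make_population_model <- function(cond, between_loading_delta = 0.5) {
  cond <- as.list(cond)
  req <- c("structural_form", "noniso_position", "icc", "n_noniso_items")
  if (!all(req %in% names(cond)))
    stop("cond is missing fields: ",
         paste(setdiff(req, names(cond)), collapse = ", "))
  if (!cond$structural_form %in% .grid_levels$structural_form)
    stop("unknown structural_form: ", cond$structural_form)
  if (!cond$noniso_position %in% .grid_levels$noniso_position)
    stop("unknown noniso_position: ", cond$noniso_position)
  k <- as.integer(cond$n_noniso_items)
  if (k < 0L || k > 3L)
    stop("n_noniso_items must be in 0..3 (at most half of the 6 items)")
  if (between_loading_delta < 0)
    stop("between_loading_delta must be non-negative")

  item_construct <- rep(1:2, each = 6L)
  referent_items <- c(1L, 7L)
  beta_w <- if (cond$structural_form == "homologous") 0.44 else 0.31
  beta_b <- 0.44

  lambda_w <- rep(1, 12L)
  lambda_b <- rep(1, 12L)
  # non-isomorphic items: highest-numbered non-referent items of the target
  # construct, so the referent is never selected
  noniso_items <- integer(0)
  if (k > 0L) {
    block <- if (cond$noniso_position == "exogenous") 1:6 else 7:12
    candidates <- setdiff(block, referent_items)
    noniso_items <- sort(utils::tail(candidates, k))
    lambda_b[noniso_items] <- 1 + between_loading_delta
  }

  share <- .between_factor_share()
  cal_exo <- calibrate_between_variances(cond$icc, within_total_variance = 2,
                                         factor_share = share)
  w_endo <- 2 + beta_w^2  # endogenous within total: loadings 1, probit resid 1
  cal_endo <- calibrate_between_variances(cond$icc,
                                          within_total_variance = w_endo,
                                          factor_share = share)
  phi_b_exo <- cal_exo$factor_variance
  zeta_b_endo <- cal_endo$factor_variance - beta_b^2 * phi_b_exo
  if (cond$icc > 0 && zeta_b_endo <= 0)
    stop("calibration produced non-positive endogenous between residual variance")
  theta_b <- c(rep(cal_exo$indicator_residual_variance, 6L),
               rep(cal_endo$indicator_residual_variance, 6L))

  model <- list(
    lambda_within = lambda_w,
    lambda_between = lambda_b,
    item_construct = item_construct,
    referent_items = referent_items,
    noniso_items = noniso_items,
    phi_w_exo = 1.0,
    zeta_w_endo = 1.0,
    phi_b_exo = phi_b_exo,
    zeta_b_endo = zeta_b_endo,
    theta_b = theta_b,
    tau = rep(0, 12L),
    beta_within = beta_w,
    beta_between = beta_b,
    between_loading_delta = between_loading_delta,
    icc = cond$icc
  )
  class(model) <- "msem_population"
  model
}

#' @export
print.msem_population <- function(x, ...) {
  cat("Two-level probit SEM population model\n")
  cat("  beta_within =", x$beta_within, " beta_between =", x$beta_between, "\n")
  cat("  phi_b_exo =", round(x$phi_b_exo, 4),
      " zeta_b_endo =", round(x$zeta_b_endo, 4),
      " (target indicator ICC ", x$icc, ")\n", sep = "")
  if (length(x$noniso_items))
    cat("  non-isomorphic items:", paste(x$noniso_items, collapse = ", "),
        "with between loading", 1 + x$between_loading_delta, "\n")
  else cat("  fully isomorphic (all loadings 1 at both levels)\n")
  invisible(x)
}

#' Export a condition grid as a tab-delimited table
#'
#' @param grid result of \code{build_condition_grid}.
#' @param path output file.
#' @export
write_grid <- function(grid, path) {
  utils::write.table(as.data.frame(grid), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
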