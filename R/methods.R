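#' @export
print.msem_fit <- function(x, ...) {
  cat("Bayesian two-level probit SEM fit (", x$template$approach,
      " approach)\n", sep = "")
  cat("  ", x$data_dims$J, " clusters x ", x$data_dims$n, " units, ",
      x$data_dims$I, " items\n", sep = "")
  cat("  chains:", x$n_chains, " iterations:", x$iterations,
      " burn-in:", x$burn_in, "\n")
  cat("  converged:", x$converged,
      " (max PSR ", round(max(x$psr, na.rm = TRUE), 3), ")",
      "  admissible:", x$admissible, "\n")
  if (length(x$template$constrained_items))
    cat("  cross-level equality on items:",
        paste(x$template$constrained_items, collapse = ", "), "\n")
  invisible(x)
}

#' Posterior summary table of a fitted model
#'
#' @param object \code{msem_fit}.
#' @param free_only drop parameters that were fixed by the template.
#' @param ... unused.
#' @return data.frame with posterior mean, SD, 95\% equal-tailed credible
#'   interval and PSR per parameter (class \code{"summary.msem_fit"}).
#' @export
summary.msem_fit <- function(object, free_only = TRUE, ...) {
  keep <- if (free_only) object$free else rep(TRUE, length(object$parameters))
  out <- data.frame(
    parameter = object$parameters[keep],
    mean = unname(object$posterior_mean[keep]),
    sd = unname(object$posterior_sd[keep]),
    ci_lower = unname(object$credible_interval_95[keep, "lower"]),
    ci_upper = unname(object$credible_interval_95[keep, "upper"]),
    psr = unname(object$psr[object$parameters[keep]]),
    stringsAsFactors = FALSE
  )
  class(out) <- c("summary.msem_fit", "data.frame")
  out
}

#' @export
print.summary.msem_fit <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], round, digits = digits)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.msem_fit <- function(object, free_only = TRUE, ...) {
  keep <- if (free_only) object$free else rep(TRUE, length(object$parameters))
  object$posterior_mean[keep]
}

#' Trace plots of selected parameters
#'
#' @param x \code{msem_fit}.
#' @param pars parameter names (default: structural paths and factor
#'   variances).
#' @param ... passed to \code{matplot}.
#' @export
plot.msem_fit <- function(x, pars = NULL, ...) {
  if (is.null(pars)) {
    cand <- c("beta_w", "beta_b", "phi_w_exo", "phi_b_exo")
    pars <- intersect(cand, x$parameters[x$free])
    if (!length(pars)) pars <- x$parameters[x$free][1:min(4, sum(x$free))]
  }
  old <- graphics::par(mfrow = c(length(pars), 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (p in pars) {
    tr <- sapply(x$draws, function(d) d[, p])
    graphics::matplot(tr, type = "l", lty = 1, ylab = p, xlab = "", ...)
  }
  invisible(x)
}

#' Simulate replicated datasets from the posterior
#'
#' Draws parameter vectors from the retained posterior sample and generates a
#' replicated dataset from each, with the dimensions of the original fit.
#' This is the generating step of the posterior predictive check.
#'
#' @param object \code{msem_fit}.
#' @param nsim number of replicated datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of \code{msem_data} objects.
#' @importFrom stats simulate
#' @export
simulate.msem_fit <- function(object, nsim = 1, seed = 1L, ...) {
  all_draws <- do.call(rbind, object$draws)
  set.seed(seed)
  rows <- sample.int(nrow(all_draws), nsim, replace = nsim > nrow(all_draws))
  dims <- object$data_dims
  cond <- list(n_clusters = dims$J, cluster_size = dims$n)
  seeds <- sample.int(.Machine$integer.max %/% 2L, nsim)
  lapply(seq_len(nsim), function(s) {
    pop <- .population_from_draw(all_draws[rows[s], ], object$template)
    simulate_dataset(pop, cond, seed = seeds[s])
  })
}

# build a generating model from one posterior draw (named vector)
.population_from_draw <- function(draw, template) {
  I <- template$n_items
  C <- template$n_constructs
  lam_w <- draw[sprintf("lambda_w[%d]", seq_len(I))]
  lam_b <- draw[sprintf("lambda_b[%d]", seq_len(I))]
  tau <- draw[sprintf("tau[%d]", seq_len(I))]
  theta <- draw[sprintf("theta_b[%d]", seq_len(I))]
  model <- list(
    lambda_within = unname(lam_w),
    lambda_between = unname(lam_b),
    item_construct = template$item_construct,
    referent_items = template$referent_items,
    noniso_items = integer(0),
    phi_w_exo = unname(draw["phi_w_exo"]),
    zeta_w_endo = if (C == 2) unname(draw["zeta_w_endo"]) else 1,
    phi_b_exo = if (template$between) unname(draw["phi_b_exo"]) else 0,
    zeta_b_endo = if (template$between && C == 2) unname(draw["zeta_b_endo"]) else 0,
    theta_b = if (template$between) unname(theta) else rep(0, I),
    tau = unname(tau),
    beta_within = if (C == 2) unname(draw["beta_w"]) else 0,
    beta_between = if (C == 2) unname(draw["beta_b"]) else 0,
    between_loading_delta = NA_real_,
    icc = NA_real_
  )
  class(model) <- "msem_population"
  model
}
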