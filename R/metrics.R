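#' Relative bias in percent
#'
#' \eqn{100 (\hat\theta - \theta) / \theta}: the mean estimate minus the true
#' parameter, divided by the true parameter.
#'
#' @param mean_estimate replication-averaged estimate.
#' @param true_value generating value (non-zero).
#' @return percent.
#' @examples
#' relative_bias(0.594, 0.44)  # 35
#' @export
relative_bias <- function(mean_estimate, true_value) {
  if (any(true_value == 0)) stop("relative bias is undefined for a true value of 0")
  100 * (mean_estimate - true_value) / true_value
}

#' Classify relative bias
#'
#' Absolute relative bias below 10\% is acceptable, between 10 and 20\%
#' (inclusive at both boundaries) substantial, above 20\% unacceptable.
#'
#' @param rb relative bias in percent (vectorized).
#' @return factor with levels acceptable, substantial, unacceptable.
#' @export
classify_bias <- function(rb) {
  a <- abs(rb)
  out <- ifelse(a < 10, "acceptable",
         ifelse(a <= 20, "substantial", "unacceptable"))
  factor(out, levels = c("acceptable", "substantial", "unacceptable"))
}

#' Signed sum of loading errors
#'
#' Sum over the free (non-referent) loadings of a construct at one level of
#' (mean estimate - true value), sign preserved; since within a condition
#' the loading errors share a direction, the sum conveys both magnitude and
#' direction.
#'
#' @param mean_estimates replication-averaged loading estimates (referent
#'   excluded).
#' @param true_values matching generating loadings.
#' @return signed sum.
#' @export
sum_loading_bias <- function(mean_estimates, true_values) {
  if (length(mean_estimates) != length(true_values))
    stop("estimate and truth vectors must have equal length")
  sum(mean_estimates - true_values)
}

#' Coverage of credible intervals
#'
#' @param intervals two-column matrix (lower, upper) or list of length-2
#'   vectors; one row per replication.
#' @param true_value generating value.
#' @return proportion of intervals containing the truth.
#' @export
coverage_rate <- function(intervals, true_value) {
  if (is.list(intervals)) intervals <- do.call(rbind, intervals)
  intervals <- as.matrix(intervals)
  if (nrow(intervals) < 1L) stop("at least one interval is required")
  mean(intervals[, 1] <= true_value & true_value <= intervals[, 2])
}

# map population model to the sampler's parameter names
population_parameter_vector <- function(model, template) {
  I <- template$n_items
  setNames(
    c(model$lambda_within, model$lambda_between, model$tau, model$theta_b,
      model$phi_w_exo, model$zeta_w_endo, model$phi_b_exo, model$zeta_b_endo,
      model$beta_within, model$beta_between),
    .param_names(template))
}

#' Aggregate replicated fits of one design cell
#'
#' Computes the per-cell performance statistics: convergence and
#' admissibility rates, mean posterior predictive p-value and the proportion
#' of replications with PPP > 0.5 (when fits carry a \code{ppp}), and, per
#' construct and level, the signed loading-sum bias, the relative bias (%) of
#' the latent (residual) variance and its 95\% interval coverage, plus the
#' relative bias and coverage of the structural paths.  Replications flagged
#' non-converged or inadmissible are counted in the rates and excluded from
#' the bias/coverage aggregates.
#'
#' @param fits list of \code{msem_fit} (optionally with a \code{ppp} element
#'   attached by \code{\link{compute_ppp}}).
#' @param model generating \code{msem_population} of the cell.
#' @param cell the condition (grid row or list); stored in the result.
#' @param point_estimate per-replication point estimate fed into the bias
#'   aggregates: the posterior median (default; the point estimate reported
#'   by the estimation software the study design mirrors, and robust to the
#'   right skew of variance posteriors) or the posterior mean.
#' @return object of class \code{"msem_cell_summary"}.
#' @export
summarize_cell <- function(fits, model, cell,
                           point_estimate = c("median", "mean")) {
  stopifnot(length(fits) >= 1L)
  point_estimate <- match.arg(point_estimate)
  truth <- population_parameter_vector(model, fits[[1]]$template)
  usable <- vapply(fits, function(f) f$converged && f$admissible, logical(1))
  if (!any(usable)) stop("no converged, admissible fits to aggregate")
  use <- fits[usable]

  est <- do.call(rbind, lapply(use, function(f)
    if (point_estimate == "median") f$posterior_median else f$posterior_mean))
  mean_est <- colMeans(est)
  ci_lo <- do.call(rbind, lapply(use, function(f) f$credible_interval_95[, "lower"]))
  ci_hi <- do.call(rbind, lapply(use, function(f) f$credible_interval_95[, "upper"]))

  template <- use[[1]]$template
  g <- template$item_construct
  ref <- template$referent_items
  free_items <- function(construct) setdiff(which(g == construct), ref)

  load_bias <- function(level, construct) {
    idx <- sprintf("lambda_%s[%d]", level, free_items(construct))
    sum_loading_bias(mean_est[idx], truth[idx])
  }
  var_stats <- function(par) {
    list(rel_bias = relative_bias(mean_est[par], truth[par]),
         coverage = coverage_rate(cbind(ci_lo[, par], ci_hi[, par]),
                                  truth[par]))
  }
  vw1 <- var_stats("phi_w_exo");  vw2 <- var_stats("zeta_w_endo")
  vb1 <- var_stats("phi_b_exo");  vb2 <- var_stats("zeta_b_endo")
  bw <- var_stats("beta_w");      bb <- var_stats("beta_b")

  ppp <- vapply(fits, function(f) f$ppp %||% NA_real_, numeric(1))
  rb <- c(within_exo_var = unname(vw1$rel_bias),
          within_endo_resid = unname(vw2$rel_bias),
          between_exo_var = unname(vb1$rel_bias),
          between_endo_resid = unname(vb2$rel_bias),
          beta_within = unname(bw$rel_bias),
          beta_between = unname(bb$rel_bias))

  out <- list(
    cell = as.list(cell),
    n_reps = length(fits),
    n_used = length(use),
    convergence_rate = mean(vapply(fits, function(f) f$converged, logical(1))),
    admissibility_rate = mean(vapply(fits, function(f) f$admissible, logical(1))),
    mean_ppp = if (all(is.na(ppp))) NA_real_ else mean(ppp, na.rm = TRUE),
    prop_ppp_above_half =
      if (all(is.na(ppp))) NA_real_ else mean(ppp > 0.5, na.rm = TRUE),
    loading_sum_bias = c(
      within_exo = load_bias("w", 1), within_endo = load_bias("w", 2),
      between_exo = load_bias("b", 1), between_endo = load_bias("b", 2)),
    variance_rel_bias = rb[1:4],
    variance_coverage = c(
      within_exo_var = unname(vw1$coverage),
      within_endo_resid = unname(vw2$coverage),
      between_exo_var = unname(vb1$coverage),
      between_endo_resid = unname(vb2$coverage)),
    beta_rel_bias = rb[5:6],
    beta_coverage = c(beta_within = unname(bw$coverage),
                      beta_between = unname(bb$coverage)),
    bias_class = classify_bias(rb),
    # per-replication posterior means, for Monte Carlo standard errors
    replication_means = est
  )
  names(out$bias_class) <- names(rb)
  class(out) <- "msem_cell_summary"
  out
}

#' @export
print.msem_cell_summary <- function(x, ...) {
  cat("Cell summary (", x$n_used, "/", x$n_reps, " usable replications)\n",
      sep = "")
  cat("  beta rel bias (%): within ", round(x$beta_rel_bias[1], 1),
      ", between ", round(x$beta_rel_bias[2], 1), "\n", sep = "")
  cat("  beta coverage: within ", round(x$beta_coverage[1], 2),
      ", between ", round(x$beta_coverage[2], 2), "\n", sep = "")
  cat("  variance rel bias (%):",
      paste(names(x$variance_rel_bias),
            round(x$variance_rel_bias), collapse = ", "), "\n")
  cat("  loading sum bias:",
      paste(names(x$loading_sum_bias),
            round(x$loading_sum_bias, 2), collapse = ", "), "\n")
  if (!is.na(x$mean_ppp))
    cat("  mean PPP ", round(x$mean_ppp, 2), ", prop > 0.5: ",
        round(x$prop_ppp_above_half, 2), "\n", sep = "")
  invisible(x)
}
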