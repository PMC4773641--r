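#' Proportional scale reduction (PSR) across chain segments
#'
#' Gelman-Rubin style statistic comparing between- and within-segment
#' variance of MCMC draws.  With \eqn{m} segments of length \eqn{n},
#' \eqn{W} is the mean within-segment variance and \eqn{B/n} the variance of
#' the segment means, and
#' \deqn{PSR = \sqrt{(W + B/n) / W} \ge 1,}
#' so identical segments give exactly 1.  Zero-variance (constant) segments
#' are assigned PSR 1 by convention.
#'
#' @param draw_segments list of >= 2 numeric matrices of identical dimension
#'   (iterations x parameters); plain vectors are treated as one-column
#'   matrices.
#' @return named numeric vector of PSR values, one per parameter (column).
#' @examples
#' a <- matrix(rnorm(1000), 500)
#' compute_psr(list(a, a))  # identical segments -> 1
#' @export
compute_psr <- function(draw_segments) {
  if (!is.list(draw_segments) || length(draw_segments) < 2L)
    stop("at least 2 draw segments are required")
  segs <- lapply(draw_segments, function(s) {
    s <- as.matrix(s)
    if (nrow(s) < 10L) stop("segments must have length >= 10")
    s
  })
  dims <- vapply(segs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("segments must have identical dimensions")
  n <- dims[1, 1]
  means <- sapply(segs, colMeans)                       # P x m
  vars <- sapply(segs, function(s) apply(s, 2L, var))   # P x m
  means <- matrix(means, ncol = length(segs))
  vars <- matrix(vars, ncol = length(segs))
  W <- rowMeans(vars)
  B_over_n <- apply(means, 1L, var)
  psr <- sqrt((W + B_over_n) / W)
  psr[W < .Machine$double.eps & B_over_n < sqrt(.Machine$double.eps)] <- 1
  psr[W < .Machine$double.eps & B_over_n >= sqrt(.Machine$double.eps)] <- Inf
  names(psr) <- colnames(segs[[1]])
  psr
}

#' Kolmogorov-Smirnov comparison of chains
#'
#' Two-sample KS tests per free parameter comparing the retained draws of
#' the first two chains, thinned to every 10th draw to mitigate
#' autocorrelation.  Mirrors the practice of confirming multi-chain
#' agreement of posterior distributions.
#'
#' @param fit \code{msem_fit} with at least two chains.
#' @param thin thinning applied before the test.
#' @return named numeric vector of p-values per free parameter.
#' @export
ks_between_chains <- function(fit, thin = 10L) {
  stopifnot(inherits(fit, "msem_fit"))
  if (fit$n_chains < 2L)
    stop("KS comparison requires at least two chains")
  idx <- seq(1L, nrow(fit$draws[[1]]), by = thin)
  pars <- fit$parameters[fit$free]
  sapply(pars, function(p) {
    a <- fit$draws[[1]][idx, p]
    b <- fit$draws[[2]][idx, p]
    if (sd(a) == 0 && sd(b) == 0 && a[1] == b[1]) return(1)
    suppressWarnings(stats::ks.test(a, b)$p.value)
  })
}

# model-implied moments of the latent responses for one parameter draw:
# per-item P(y = 1) and same-person pairwise orthant probabilities
.implied_cell_probs <- function(pop) {
  I <- length(pop$lambda_within)
  g <- pop$item_construct
  C <- max(g)
  phi_w <- if (C == 2)
    matrix(c(pop$phi_w_exo, rep(pop$beta_within * pop$phi_w_exo, 2),
             pop$beta_within^2 * pop$phi_w_exo + pop$zeta_w_endo), 2)
  else matrix(pop$phi_w_exo)
  phi_b <- if (C == 2)
    matrix(c(pop$phi_b_exo, rep(pop$beta_between * pop$phi_b_exo, 2),
             pop$beta_between^2 * pop$phi_b_exo + pop$zeta_b_endo), 2)
  else matrix(pop$phi_b_exo)
  lw <- pop$lambda_within; lb <- pop$lambda_between
  # latent-response covariance for one person
  S <- outer(seq_len(I), seq_len(I), function(i, k)
    lw[i] * lw[k] * phi_w[cbind(g[i], g[k])] +
    lb[i] * lb[k] * phi_b[cbind(g[i], g[k])])
  diag(S) <- diag(S) + pop$theta_b + 1
  mu <- -pop$tau                       # E[y*] - threshold
  z <- mu / sqrt(diag(S))
  p_one <- pnorm(z)
  R <- stats::cov2cor(S)
  pairs <- utils::combn(I, 2L)
  p11 <- apply(pairs, 2L, function(ik) {
    i <- ik[1]; k <- ik[2]
    mvtnorm::pmvnorm(lower = c(-z[i], -z[k]), upper = Inf,
                     corr = matrix(c(1, R[i, k], R[i, k], 1), 2))[1]
  })
  list(p_one = p_one, pairs = pairs, p11 = p11)
}

# likelihood-ratio discrepancy between observed counts and the implied
# probabilities: item margins plus same-person pairwise 2x2 tables
.lr_discrepancy <- function(y, imp) {
  N <- nrow(y)
  g2 <- function(o, e) {
    e <- pmax(e, 1e-10)
    sum(ifelse(o > 0, 2 * o * log(o / e), 0))
  }
  d <- 0
  n1 <- colSums(y)
  for (i in seq_along(imp$p_one))
    d <- d + g2(c(n1[i], N - n1[i]), N * c(imp$p_one[i], 1 - imp$p_one[i]))
  for (j in seq_len(ncol(imp$pairs))) {
    i <- imp$pairs[1, j]; k <- imp$pairs[2, j]
    n11 <- sum(y[, i] & y[, k])
    o <- c(n11, n1[i] - n11, n1[k] - n11, N - n1[i] - n1[k] + n11)
    p11 <- imp$p11[j]
    e <- N * c(p11, imp$p_one[i] - p11, imp$p_one[k] - p11,
               1 - imp$p_one[i] - imp$p_one[k] + p11)
    d <- d + g2(o, e)
  }
  d
}

#' Posterior predictive p-value
#'
#' For a subset of retained draws, computes a likelihood-ratio discrepancy
#' \eqn{D} comparing observed against model-implied frequencies of the item
#' margins and all same-person pairwise 2x2 tables, simulates a replicated
#' dataset from the same draw, and reports the proportion of draws with
#' \eqn{D(rep) \ge D(obs)}.  Values near 0.5 indicate a well-fitting model;
#' values near 0 indicate misfit.
#'
#' @param fit \code{msem_fit}.
#' @param data the \code{msem_data} the model was fitted to.
#' @param n_draws number of posterior draws used (evenly spaced over the
#'   retained sample).
#' @param seed integer seed for the replicated datasets.
#' @return proportion in [0, 1].
#' @export
compute_ppp <- function(fit, data, n_draws = 100L, seed = 1L) {
  stopifnot(inherits(fit, "msem_fit"), inherits(data, "msem_data"))
  all_draws <- do.call(rbind, fit$draws)
  if (n_draws > nrow(all_draws))
    stop("n_draws exceeds the number of retained draws")
  rows <- round(seq(1L, nrow(all_draws), length.out = n_draws))
  dims <- fit$data_dims
  cond <- list(n_clusters = dims$J, cluster_size = dims$n)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max %/% 2L, n_draws)
  y_obs <- data$responses
  exceed <- logical(n_draws)
  for (s in seq_len(n_draws)) {
    pop <- .population_from_draw(all_draws[rows[s], ], fit$template)
    imp <- .implied_cell_probs(pop)
    d_obs <- .lr_discrepancy(y_obs, imp)
    y_rep <- simulate_dataset(pop, cond, seed = rep_seeds[s])$responses
    d_rep <- .lr_discrepancy(y_rep, imp)
    exceed[s] <- d_rep >= d_obs
  }
  mean(exceed)
}
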