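#' Model template for the two-level binary-indicator SEM
#'
#' Describes the measurement structure and which parameters the fit equates
#' across levels.  The default template is the study's 2-constructs x 6-items
#' layout with referent items 1 and 7 (loadings fixed at 1 on both levels).
#' Under the \code{"constrained"} approach, the within and between loadings
#' of \code{constrained_items} are equated (a single loading per item,
#' sampled from the product of its within- and between-level full
#' conditionals); under \code{"free"} the set must be empty and all
#' non-referent loadings are estimated separately per level.
#'
#' @param approach \code{"free"} or \code{"constrained"}.
#' @param constrained_items integer item indices whose loadings are equated
#'   across levels (must exclude referent items; empty for \code{"free"}).
#' @param item_construct construct index (1 or 2) per item.
#' @param referent_items one item per construct whose loading is fixed at 1
#'   on both levels.
#' @param between logical; include the between-level measurement model
#'   (random intercepts, between loadings/variances).  Disabled only for
#'   reduced single-level test models.
#' @param fixed named list of parameters held fixed at given values (used by
#'   validation studies): item-level entries \code{lambda_w}, \code{lambda_b},
#'   \code{tau}, \code{theta_b} are numeric vectors named by item index;
#'   scalar entries \code{phi_w_exo}, \code{zeta_w_endo}, \code{phi_b_exo},
#'   \code{zeta_b_endo}, \code{beta_w}, \code{beta_b}.
#' @return object of class \code{"msem_template"}.
#' @export
msem_template <- function(approach = c("free", "constrained"),
                          constrained_items = integer(0),
                          item_construct = rep(1:2, each = 6L),
                          referent_items = c(1L, 7L),
                          between = TRUE,
                          fixed = list()) {
  approach <- match.arg(approach)
  item_construct <- as.integer(item_construct)
  I <- length(item_construct)
  C <- length(unique(item_construct))
  if (!all(sort(unique(item_construct)) == seq_len(C)))
    stop("item_construct must use consecutive construct indices 1..C")
  if (C > 2L) stop("at most two constructs are supported")
  if (length(referent_items) != C)
    stop("exactly one referent item per construct is required")
  if (any(item_construct[referent_items] != seq_len(C)))
    stop("referent_items must list the referent of construct 1, then 2")
  constrained_items <- as.integer(constrained_items)
  if (approach == "free" && length(constrained_items))
    stop("the free approach estimates all loadings; constrained_items must be empty")
  if (any(constrained_items %in% referent_items))
    stop("referent items cannot be constrained (their loadings are fixed at 1)")
  if (any(!constrained_items %in% seq_len(I)))
    stop("constrained_items out of range")
  ok <- c("lambda_w", "lambda_b", "tau", "theta_b", "phi_w_exo",
          "zeta_w_endo", "phi_b_exo", "zeta_b_endo", "beta_w", "beta_b")
  if (length(fixed) && (is.null(names(fixed)) || any(!names(fixed) %in% ok)))
    stop("fixed entries must be named among: ", paste(ok, collapse = ", "))
  structure(list(approach = approach,
                 constrained_items = constrained_items,
                 item_construct = item_construct,
                 referent_items = as.integer(referent_items),
                 n_items = I, n_constructs = C,
                 between = isTRUE(between),
                 fixed = fixed),
            class = "msem_template")
}

#' Template implied by a design cell
#'
#' Convenience wrapper: the constrained approach equates exactly the items
#' that are non-isomorphic by design in that cell; the free approach equates
#' nothing.
#'
#' @param cond grid row (needs \code{modeling_approach},
#'   \code{noniso_position}, \code{n_noniso_items}).
#' @param model matching \code{msem_population}; supplies the designed
#'   non-isomorphic item set.
#' @return \code{msem_template}.
#' @export
template_for_condition <- function(cond, model) {
  cond <- as.list(cond)
  if (cond$modeling_approach == "free")
    msem_template("free")
  else
    msem_template("constrained", constrained_items = model$noniso_items)
}

#' Prior specification
#'
#' The study's uninformative priors: loadings N(1, 0.1) (variance, not SD) on
#' both levels; variances flat on (0, Inf) (the inverse-gamma limit, no
#' tuning constants); between-level thresholds flat N(0, Inf); structural
#' paths N(mean, 0.1) with the mean supplied per cell (the generating value,
#' so the prior mass sits in the region of the population value).
#'
#' @param beta_w_mean,beta_b_mean prior means of the structural paths
#'   (condition-dependent; no default on purpose).
#' @param loading_mean,loading_var loading prior moments.
#' @param beta_var prior variance of the structural paths.
#' @return object of class \code{"msem_priors"}.
#' @export
prior_spec <- function(beta_w_mean, beta_b_mean,
                       loading_mean = 1, loading_var = 0.1,
                       beta_var = 0.1) {
  if (missing(beta_w_mean) || missing(beta_b_mean))
    stop("beta prior means are condition-dependent and must be supplied")
  structure(list(loading_mean = loading_mean, loading_var = loading_var,
                 beta_w_mean = beta_w_mean, beta_b_mean = beta_b_mean,
                 beta_var = beta_var),
            class = "msem_priors")
}

#' Priors implied by a design cell (means at the generating values)
#' @param model \code{msem_population}.
#' @export
priors_for_model <- function(model) {
  prior_spec(beta_w_mean = model$beta_within, beta_b_mean = model$beta_between)
}

#' MCMC settings
#'
#' A single chain with PSR-based early stopping is the default; two or more
#' chains run in lockstep and PSR compares chains.  Burn-in discards the
#' first \code{burn_in_fraction} of iterations at the point of stopping.
#'
#' @param n_chains number of chains (diagnostics mode: 2).
#' @param max_iterations hard cap on iterations per chain.
#' @param burn_in_fraction fraction discarded as burn-in, in (0, 1).
#' @param thinning keep every \code{thinning}-th retained draw.
#' @param psr_threshold convergence declared when all free-parameter PSR
#'   values drop below this.
#' @param min_iterations iterations before the first convergence check.
#' @param check_interval iterations between convergence checks.
#' @param seed chain c uses \code{seed + c - 1}.
#' @return object of class \code{"msem_mcmc_settings"}.
#' @export
mcmc_settings <- function(n_chains = 1L, max_iterations = 2000L,
                          burn_in_fraction = 0.5, thinning = 1L,
                          psr_threshold = 1.05, min_iterations = 500L,
                          check_interval = 250L, seed = 1L) {
  stopifnot(max_iterations > 0, burn_in_fraction > 0, burn_in_fraction < 1,
            thinning >= 1, n_chains >= 1)
  structure(list(n_chains = as.integer(n_chains),
                 max_iterations = as.integer(max_iterations),
                 burn_in_fraction = burn_in_fraction,
                 thinning = as.integer(thinning),
                 psr_threshold = psr_threshold,
                 min_iterations = as.integer(min_iterations),
                 check_interval = as.integer(check_interval),
                 seed = as.integer(seed)),
            class = "msem_mcmc_settings")
}

# parameter vector layout matching the sampler's draw columns
.param_names <- function(template) {
  I <- template$n_items
  C <- template$n_constructs
  nm_w <- if (C == 2) c("phi_w_exo", "zeta_w_endo") else "phi_w_exo"
  nm_b <- if (C == 2) c("phi_b_exo", "zeta_b_endo") else "phi_b_exo"
  c(sprintf("lambda_w[%d]", seq_len(I)),
    sprintf("lambda_b[%d]", seq_len(I)),
    sprintf("tau[%d]", seq_len(I)),
    sprintf("theta_b[%d]", seq_len(I)),
    nm_w, nm_b, "beta_w", "beta_b")
}

# initial values, fixed masks and fixed values from template
.build_par <- function(template) {
  I <- template$n_items
  C <- template$n_constructs
  fx <- template$fixed
  lam_w <- rep(1, I); lam_b <- rep(1, I)
  mu <- rep(0, I); theta <- rep(0.2, I)
  phi_w <- rep(1, C); phi_b <- rep(0.2, C)
  beta_w <- 0; beta_b <- 0
  f_lam_w <- f_lam_b <- rep(FALSE, I)
  f_lam_w[template$referent_items] <- TRUE
  f_lam_b[template$referent_items] <- TRUE
  f_mu <- f_theta <- rep(FALSE, I)
  f_phi_w <- rep(FALSE, C); f_phi_b <- rep(FALSE, C)
  f_beta_w <- f_beta_b <- (C != 2L)
  set_items <- function(values, target, mask) {
    idx <- as.integer(names(values))
    if (any(is.na(idx)) || any(!idx %in% seq_len(I)))
      stop("fixed item entries must be named by item index")
    target[idx] <- as.numeric(values)
    mask[idx] <- TRUE
    list(target, mask)
  }
  if (!is.null(fx$lambda_w)) { r <- set_items(fx$lambda_w, lam_w, f_lam_w); lam_w <- r[[1]]; f_lam_w <- r[[2]] }
  if (!is.null(fx$lambda_b)) { r <- set_items(fx$lambda_b, lam_b, f_lam_b); lam_b <- r[[1]]; f_lam_b <- r[[2]] }
  if (!is.null(fx$tau)) {  # internal intercepts are mu = -tau
    idx <- as.integer(names(fx$tau))
    if (any(is.na(idx)) || any(!idx %in% seq_len(I)))
      stop("fixed item entries must be named by item index")
    mu[idx] <- -as.numeric(fx$tau)
    f_mu[idx] <- TRUE
  }
  if (!is.null(fx$theta_b))  { r <- set_items(fx$theta_b, theta, f_theta); theta <- r[[1]]; f_theta <- r[[2]] }
  if (!is.null(fx$phi_w_exo))   { phi_w[1] <- fx$phi_w_exo; f_phi_w[1] <- TRUE }
  if (!is.null(fx$zeta_w_endo) && C == 2) { phi_w[2] <- fx$zeta_w_endo; f_phi_w[2] <- TRUE }
  if (!is.null(fx$phi_b_exo))   { phi_b[1] <- fx$phi_b_exo; f_phi_b[1] <- TRUE }
  if (!is.null(fx$zeta_b_endo) && C == 2) { phi_b[2] <- fx$zeta_b_endo; f_phi_b[2] <- TRUE }
  if (!is.null(fx$beta_w)) { beta_w <- fx$beta_w; f_beta_w <- TRUE }
  if (!is.null(fx$beta_b)) { beta_b <- fx$beta_b; f_beta_b <- TRUE }
  list(par = list(lambda_w = lam_w, lambda_b = lam_b, mu = mu,
                  theta_b = theta, phi_w = phi_w, phi_b = phi_b,
                  beta_w = beta_w, beta_b = beta_b),
       fixed = list(lambda_w = f_lam_w, lambda_b = f_lam_b, mu = f_mu,
                    theta_b = f_theta, phi_w = f_phi_w, phi_b = f_phi_b,
                    beta_w = f_beta_w, beta_b = f_beta_b))
}

# free-parameter mask over draw columns
.free_mask <- function(template, built) {
  I <- template$n_items
  C <- template$n_constructs
  fx <- built$fixed
  con <- rep(FALSE, I); con[template$constrained_items] <- TRUE
  free_lam_w <- !fx$lambda_w | (con & template$between)
  free_lam_b <- (!fx$lambda_b | (con & template$between)) & template$between
  free_tau <- !fx$mu
  free_theta <- rep(template$between, I) & !fx$theta_b
  c(free_lam_w, free_lam_b, free_tau, free_theta,
    !fx$phi_w, rep(template$between, C) & !fx$phi_b,
    if (C == 2) !fx$beta_w else FALSE,
    if (C == 2) (!fx$beta_b && template$between) else FALSE)
}

#' Fit the two-level binary-indicator SEM by Gibbs sampling
#'
#' Probit measurement with truncated-normal augmentation of the latent
#' responses; full conditionals cycle over the augmented responses, within
#' factor scores, cluster random intercepts and between factor scores,
#' loadings (with cross-level equality blocks under the constrained
#' approach), between thresholds, variances, and structural paths.  All
#' conditionals are conjugate.  Convergence is monitored by the proportional
#' scale reduction (PSR) of every free parameter, checked at
#' \code{check_interval} steps with early stopping; a fit that never reaches
#' \code{psr_threshold} is returned with \code{converged = FALSE}.
#'
#' @param data \code{msem_data} (balanced clusters, binary responses).
#' @param template \code{msem_template}.
#' @param priors \code{msem_priors}.
#' @param settings \code{msem_mcmc_settings}.
#' @return object of class \code{"msem_fit"}: retained draws per chain,
#'   posterior means/SDs, equal-tailed 95\% credible intervals, per-parameter
#'   PSR at stopping, convergence and admissibility flags, iteration count.
#' @export
fit_msem <- function(data, template = msem_template("free"),
                     priors, settings = mcmc_settings()) {
  stopifnot(inherits(data, "msem_data"), inherits(template, "msem_template"),
            inherits(priors, "msem_priors"),
            inherits(settings, "msem_mcmc_settings"))
  y <- data$responses
  if (!all(y %in% c(0L, 1L))) stop("responses must be binary 0/1")
  if (ncol(y) != template$n_items)
    stop("template expects ", template$n_items, " items, data has ", ncol(y))
  cl <- as.integer(factor(data$cluster_id))
  J <- length(unique(cl))
  if (length(unique(tabulate(cl))) != 1L) stop("clusters must be balanced")
  if (J < 5L) stop("at least 5 clusters are required")

  built <- .build_par(template)
  con <- rep(FALSE, template$n_items)
  con[template$constrained_items] <- TRUE
  prior <- list(loading_mean = priors$loading_mean,
                loading_var = priors$loading_var,
                beta_w_mean = priors$beta_w_mean,
                beta_b_mean = priors$beta_b_mean,
                beta_var = priors$beta_var)
  pnames <- .param_names(template)
  free <- .free_mask(template, built)

  n_chains <- settings$n_chains
  chains <- vector("list", n_chains)
  for (ch in seq_len(n_chains))
    chains[[ch]] <- list(par = built$par, state = NULL, draws = NULL,
                         rng = NULL)
  total <- 0L
  converged <- FALSE
  psr <- setNames(rep(NA_real_, sum(free)), pnames[free])
  repeat {
    chunk <- min(settings$check_interval,
                 settings$max_iterations - total)
    if (chunk <= 0L) break
    for (ch in seq_len(n_chains)) {
      if (is.null(chains[[ch]]$rng)) {
        set.seed(settings$seed + ch - 1L)
      } else {
        assign(".Random.seed", chains[[ch]]$rng, envir = globalenv())
      }
      res <- .gibbs_msem_cpp(y, cl - 1L, J, template$item_construct - 1L,
                             template$n_constructs, template$between,
                             chunk, chains[[ch]]$par, built$fixed, con,
                             prior, chains[[ch]]$state)
      chains[[ch]]$rng <- get(".Random.seed", envir = globalenv())
      chains[[ch]]$par <- res$par
      chains[[ch]]$state <- res$state
      chains[[ch]]$draws <- rbind(chains[[ch]]$draws, res$draws)
    }
    total <- total + chunk
    if (total >= settings$min_iterations) {
      segs <- .psr_segments(chains, total, free)
      psr <- compute_psr(segs)
      names(psr) <- pnames[free]
      if (all(psr < settings$psr_threshold, na.rm = TRUE)) {
        converged <- TRUE
        break
      }
    }
  }
  if (total >= settings$max_iterations && !converged) {
    segs <- .psr_segments(chains, total, free)
    psr <- compute_psr(segs)
    names(psr) <- pnames[free]
    converged <- all(psr < settings$psr_threshold, na.rm = TRUE)
  }

  burn <- floor(settings$burn_in_fraction * total)
  keep <- seq.int(burn + 1L, total, by = settings$thinning)
  draws <- lapply(chains, function(chain) {
    d <- chain$draws[keep, , drop = FALSE]
    colnames(d) <- pnames
    d
  })
  all_draws <- do.call(rbind, draws)
  est <- colMeans(all_draws)
  med <- apply(all_draws, 2L, stats::median)
  psd <- apply(all_draws, 2L, sd)
  ci <- t(apply(all_draws, 2L, quantile, probs = c(0.025, 0.975), names = FALSE))
  colnames(ci) <- c("lower", "upper")
  var_cols <- grepl("^(theta_b|phi_|zeta_)", pnames) & free
  admissible <- all(is.finite(all_draws[, free, drop = FALSE])) &&
    all(all_draws[, var_cols, drop = FALSE] > 0)

  fit <- list(draws = draws,
              parameters = pnames, free = setNames(free, pnames),
              posterior_mean = est, posterior_median = med,
              posterior_sd = psd,
              credible_interval_95 = ci,
              psr = psr, converged = converged, admissible = admissible,
              iterations = total, burn_in = burn,
              n_chains = n_chains,
              template = template, priors = priors, settings = settings,
              data_dims = list(N = nrow(y), J = J,
                               n = nrow(y) %/% J, I = ncol(y)))
  class(fit) <- "msem_fit"
  fit
}

# second half of each chain; single chain -> split its second half in two
.psr_segments <- function(chains, total, free) {
  half <- seq.int(floor(total / 2) + 1L, total)
  if (length(chains) >= 2L) {
    lapply(chains, function(chain) chain$draws[half, free, drop = FALSE])
  } else {
    d <- chains[[1L]]$draws[half, free, drop = FALSE]
    m <- nrow(d) %/% 2L
    list(d[seq_len(m), , drop = FALSE],
         d[seq.int(m + 1L, 2L * m), , drop = FALSE])
  }
}
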