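#' Simulate a clustered binary item-response dataset
#'
#' Generates responses from a two-level probit SEM population model.  Draw
#' order is fixed (between-level factor scores and random intercepts first,
#' then within-level factor scores, then item residuals) so a given seed
#' reproduces the dataset bit-for-bit regardless of how cells are scheduled.
#'
#' Generative recipe, per cluster \eqn{c}: \eqn{\eta^b_{exo} \sim N(0,
#' \phi^b_{exo})}; \eqn{\eta^b_{endo} = \beta_b \eta^b_{exo} + N(0,
#' \zeta^b_{endo})}; item intercept \eqn{\nu_{ci} = \lambda^b_i
#' \eta^b_{g(i)} + N(0, \theta^b_i)}.  Per individual \eqn{p} in \eqn{c}:
#' \eqn{\eta^w_{exo} \sim N(0, \phi^w_{exo})}; \eqn{\eta^w_{endo} = \beta_w
#' \eta^w_{exo} + N(0, \zeta^w_{endo})}; latent response \eqn{y^*_{pi} =
#' \nu_{ci} + \lambda^w_i \eta^w_{g(i)} + N(0, 1)}; observed \eqn{y_{pi} =
#' 1} iff \eqn{y^*_{pi} > \tau_i} (strict inequality; \eqn{\tau_i = 0}).
#'
#' @param model \code{msem_population} from \code{\link{make_population_model}}.
#' @param cond condition carrying \code{n_clusters} and \code{cluster_size}
#'   (a grid row or list); \code{cell_index} and replication index are stored
#'   as provenance when present.
#' @param seed integer seed; the dataset is deterministic given
#'   (model, cond, seed).
#' @param keep_latent if TRUE, retain the latent responses and factor scores
#'   (debug mode, used by calibration diagnostics and tests).
#' @param replication optional replication index recorded in provenance.
#' @return object of class \code{"msem_data"}: list with \code{responses}
#'   (N x 12 integer matrix of 0/1), \code{cluster_id} (length N),
#'   \code{n_clusters}, \code{cluster_size}, \code{provenance}, and, with
#'   \code{keep_latent = TRUE}, \code{latent} (y*), \code{eta_w},
#'   \code{eta_b}, \code{nu}.
#' @export
simulate_dataset <- function(model, cond, seed, keep_latent = FALSE,
                             replication = NA_integer_) {
  stopifnot(inherits(model, "msem_population"))
  cond <- as.list(cond)
  J <- as.integer(cond$n_clusters)
  n <- as.integer(cond$cluster_size)
  if (is.na(J) || J < 1L || is.na(n) || n < 1L)
    stop("cond must carry positive n_clusters and cluster_size")
  vars <- c(model$phi_w_exo, model$zeta_w_endo)
  if (any(vars <= 0))
    stop("within-level variances must be strictly positive")
  if (model$phi_b_exo < 0 || model$zeta_b_endo < 0 || any(model$theta_b < 0))
    stop("between-level variances must be non-negative")

  I <- length(model$lambda_within)
  g <- model$item_construct
  N <- J * n
  cluster_id <- rep(seq_len(J), each = n)

  set.seed(as.integer(seed))
  # between level
  eta_b_exo <- rnorm(J, 0, sqrt(model$phi_b_exo))
  eta_b_endo <- model$beta_between * eta_b_exo +
    rnorm(J, 0, sqrt(model$zeta_b_endo))
  eta_b <- cbind(eta_b_exo, eta_b_endo)
  nu <- eta_b[, g, drop = FALSE] *
    matrix(model$lambda_between, J, I, byrow = TRUE) +
    matrix(rnorm(J * I, 0, rep(sqrt(model$theta_b), each = J)), J, I)
  # within level
  eta_w_exo <- rnorm(N, 0, sqrt(model$phi_w_exo))
  eta_w_endo <- model$beta_within * eta_w_exo +
    rnorm(N, 0, sqrt(model$zeta_w_endo))
  eta_w <- cbind(eta_w_exo, eta_w_endo)
  ystar <- nu[cluster_id, , drop = FALSE] +
    eta_w[, g, drop = FALSE] * matrix(model$lambda_within, N, I, byrow = TRUE) +
    matrix(rnorm(N * I), N, I)
  colnames(ystar) <- sprintf("item%02d", seq_len(I))
  y <- matrix(0L, N, I)
  y[ystar > matrix(model$tau, N, I, byrow = TRUE)] <- 1L
  colnames(y) <- colnames(ystar)

  out <- list(
    responses = y,
    cluster_id = cluster_id,
    n_clusters = J,
    cluster_size = n,
    provenance = list(cell_index = cond$cell_index %||% NA_integer_,
                      replication = replication, seed = as.integer(seed))
  )
  if (keep_latent) {
    out$latent <- ystar
    out$eta_w <- eta_w
    out$eta_b <- eta_b
    out$nu <- nu
  }
  class(out) <- "msem_data"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.msem_data <- function(x, ...) {
  cat("Clustered binary item responses:", nrow(x$responses), "rows x",
      ncol(x$responses), "items;", x$n_clusters, "clusters of",
      x$cluster_size, "\n")
  invisible(x)
}

#' One-way random-effects ICC per indicator
#'
#' Computes, for each column of a (latent) response matrix, the one-way
#' ANOVA intraclass correlation \eqn{(MS_B - MS_W) / (MS_B + (n - 1) MS_W)}
#' for balanced clusters of size \eqn{n}.  Used to validate the ICC
#' calibration of the generating model against retained latent responses.
#'
#' @param latent_responses numeric matrix (rows = observations).
#' @param cluster_id cluster membership per row (balanced).
#' @return named numeric vector of per-item ICCs.
#' @export
empirical_indicator_icc <- function(latent_responses, cluster_id) {
  latent_responses <- as.matrix(latent_responses)
  cl <- as.integer(factor(cluster_id))
  J <- length(unique(cl))
  if (J < 2L) stop("ICC undefined with a single cluster")
  n_c <- tabulate(cl)
  if (length(unique(n_c)) != 1L) stop("clusters must be balanced")
  n <- n_c[1L]
  N <- nrow(latent_responses)
  apply(latent_responses, 2L, function(yy) {
    gm <- tapply(yy, cl, mean)
    msb <- n * sum((gm - mean(yy))^2) / (J - 1)
    msw <- sum((yy - gm[cl])^2) / (N - J)
    icc <- (msb - msw) / (msb + (n - 1) * msw)
    max(icc, 0)
  })
}

#' Write / read a dataset as tab-delimited text with a JSON sidecar
#'
#' The wide layout has columns \code{cluster}, \code{unit},
#' \code{item01..item12}; provenance (cell, replication, seed) goes to
#' \code{<path>.json}.
#'
#' @param data \code{msem_data} object.
#' @param path output TSV path.
#' @rdname msem_data_io
#' @export
write_msem_data <- function(data, path) {
  stopifnot(inherits(data, "msem_data"))
  df <- data.frame(cluster = data$cluster_id,
                   unit = sequence(tabulate(data$cluster_id)),
                   data$responses, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(n_clusters = data$n_clusters, cluster_size = data$cluster_size,
               provenance = data$provenance)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @param path TSV path written by \code{write_msem_data}.
#' @rdname msem_data_io
#' @export
read_msem_data <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  items <- grep("^item", names(df), value = TRUE)
  y <- as.matrix(df[, items])
  storage.mode(y) <- "integer"
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path,
                                                          simplifyVector = TRUE)
          else NULL
  out <- list(
    responses = y,
    cluster_id = df$cluster,
    n_clusters = length(unique(df$cluster)),
    cluster_size = as.integer(nrow(y) / length(unique(df$cluster))),
    provenance = meta$provenance %||% list(cell_index = NA, replication = NA,
                                           seed = NA)
  )
  class(out) <- "msem_data"
  out
}
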